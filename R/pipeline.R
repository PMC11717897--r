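#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list; fills defaults (2.5 kb windows, minimum
#' 10 SNVs per window, 99th-percentile outliers, 5-window clusters,
#' kinship threshold 0.1, simulation mode) and collects all configuration
#' errors rather than stopping at the first. An empty file yields a
#' complete default simulation-mode config.
#'
#' @param config list or path to a YAML file.
#' @return The normalized config list (class `scan_config`), or an error
#'   listing every problem found.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    mode = "simulate",
    vcf = NULL, bed = NULL, sample_sheet = NULL,
    simulation = list(),
    focal = list(
      group1 = list(population = "germany", phenotype = "migratory"),
      group2 = list(population = "germany", phenotype = "resident")
    ),
    control = list(
      group1 = list(population = "spain"),
      group2 = list(population = "france")
    ),
    window_size = 2500, min_snvs = 10, outlier_percentile = 99,
    cluster_min = 5, kinship_threshold = 0.1,
    out_dir = "results", seed = 1L
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  errors <- character()
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(config$window_size > 0, "window_size must be positive")
  chk(config$min_snvs > 0, "min_snvs must be positive")
  chk(config$outlier_percentile > 0 && config$outlier_percentile < 100,
      "outlier_percentile must be in (0, 100)")
  chk(config$cluster_min > 0, "cluster_min must be positive")
  chk(config$kinship_threshold > 0, "kinship_threshold must be positive")
  chk(config$mode %in% c("simulate", "input"),
      sprintf("unknown mode '%s'", config$mode))
  if (identical(config$mode, "input")) {
    chk(!is.null(config$vcf), "input mode requires a vcf path")
    chk(!is.null(config$sample_sheet), "input mode requires a sample_sheet path")
  }
  same_group <- function(a, b) identical(a, b)
  chk(!same_group(config$focal$group1, config$focal$group2),
      "focal comparison groups must differ")
  chk(!(same_group(config$focal$group1, config$control$group1) &&
          same_group(config$focal$group2, config$control$group2)),
      "focal and control comparisons must reference different group pairs")
  if (identical(config$mode, "simulate") && !length(errors)) {
    scfg <- try(do.call(sim_config, config$simulation), silent = TRUE)
    if (inherits(scfg, "try-error")) {
      errors <- c(errors, paste("invalid simulation settings:",
                                attr(scfg, "condition")$message))
    } else {
      known_pop <- scfg$populations$name
      known_phe <- c(scfg$phenotypes, "none")
      for (side in c("focal", "control")) for (gn in c("group1", "group2")) {
        g <- config[[side]][[gn]]
        if (!is.null(g$population) && !g$population %in% known_pop) {
          errors <- c(errors, sprintf(
            "unknown population '%s' in %s %s", g$population, side, gn))
        }
        if (!is.null(g$phenotype) && !g$phenotype %in% known_phe) {
          errors <- c(errors, sprintf(
            "unknown phenotype '%s' in %s %s", g$phenotype, side, gn))
        }
      }
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  class(config) <- "scan_config"
  config
}

resolve_group <- function(gm, def, label) {
  ids <- gm_group(gm, population = def$population, phenotype = def$phenotype)
  if (!length(ids)) {
    stop(sprintf(
      "comparison group '%s' (population=%s, phenotype=%s) matches no samples",
      label, def$population %||% "*", def$phenotype %||% "*"
    ))
  }
  ids
}

#' Run the full differentiation scan
#'
#' Executes, in order: cohort simulation or input reading, the
#' post-calling filter chain, Method-of-Moments relatedness exclusion,
#' window statistics for the focal (between-phenotype) and control
#' (within-phenotype) comparisons, per-scaffold Z-normalization,
#' delta-FST', outlier and cluster calling, cluster summaries with
#' Tajima's D contrasts, genotype PCA (all samples and the focal
#' population alone), and a per-scaffold inversion screen. All tables are
#' written under `config$out_dir`; the run is fully determined by the
#' config and seed (re-running writes byte-identical files).
#'
#' @param config a config accepted by [validate_config()].
#' @param stages subset of `c("structure")` to skip heavier stages; the
#'   default runs everything.
#' @return Invisibly, a list with the filtered genotype matrix, window and
#'   cluster tables, kinship table, PCA results, inversion calls, the
#'   filter report and the output paths.
#' @export
run_scan <- function(config = list(), stages = c("scan", "structure")) {
  config <- validate_config(config)
  set.seed(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "simulate") {
    sim_args <- config$simulation
    sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg)
    paths <- write_cohort(cohort, out_dir)
    gm <- read_vcf(paths$vcf, paths$samples)
    bed <- paths$bed
    scaffold_map <- stats::setNames(scfg$scaffolds$chromosome, scfg$scaffolds$name)
  } else {
    gm <- read_vcf(config$vcf, config$sample_sheet)
    bed <- config$bed
    scaffold_map <- unlist(config$scaffold_map %||% list())
  }

  fc <- filter_chain(gm, bed = bed)
  gm <- fc$gm

  kin <- kinship_mom(ld_prune(gm))
  related_removed <- apply_relatedness_exclusion(
    kin, gm$samples, threshold = config$kinship_threshold
  )
  if (length(related_removed)) {
    gm <- gm_subset(gm, samples = !(gm$samples$sample %in% related_removed))
  }

  g1 <- resolve_group(gm, config$focal$group1, "focal/group1")
  g2 <- resolve_group(gm, config$focal$group2, "focal/group2")
  c1 <- resolve_group(gm, config$control$group1, "control/group1")
  c2 <- resolve_group(gm, config$control$group2, "control/group2")

  focal_w <- comparison_windows(gm, g1, g2, config$window_size, config$min_snvs)
  control_w <- comparison_windows(gm, c1, c2, config$window_size, config$min_snvs)
  windows <- delta_fst_prime(focal_w, control_w)
  windows$chromosome <- unname(scaffold_map[windows$scaffold])
  windows <- call_outliers(windows, config$outlier_percentile)
  cluster_id <- call_clusters(windows$flag, windows$scaffold, config$cluster_min)
  windows$cluster <- cluster_id
  clusters <- summarize_clusters(windows, cluster_id)
  if (nrow(clusters)) {
    clusters$p_tajima_d1 <- clusters$p_tajima_d2 <- NA_real_
    for (i in seq_len(nrow(clusters))) {
      k <- which(clusters$cluster_id[i] ==
                   sprintf("%s_cluster%d", windows$scaffold, cluster_id))
      if (sum(!is.na(windows$tajima_d1[k])) >= 2) {
        clusters$p_tajima_d1[i] <-
          compare_cluster_tajimas_d(windows$tajima_d1[k], windows$tajima_d1)$p_value
        clusters$p_tajima_d2[i] <-
          compare_cluster_tajimas_d(windows$tajima_d2[k], windows$tajima_d2)$p_value
      }
    }
  }

  pca_all <- pca_focal <- NULL
  inversions <- list()
  if ("structure" %in% stages) {
    pca_all <- pca_genotypes(gm)
    focal_ids <- union(g1, g2)
    pca_focal <- pca_genotypes(gm, samples = focal_ids)
    inversions <- lapply(unique(gm$sites$scaffold), function(s) {
      detect_inversion_signature(gm, s)
    })
    names(inversions) <- unique(gm$sites$scaffold)
  }

  # -- outputs ---------------------------------------------------------
  tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths_out <- list(
    windows = tsv(windows, "windows.tsv"),
    clusters = tsv(clusters, "clusters.tsv"),
    kinship = tsv(kin, "kinship.tsv"),
    filter_report = tsv(fc$report, "filter_report.tsv")
  )
  outl <- windows[!is.na(windows$flag) & windows$flag == "outlier", ]
  writeLines(
    sprintf("%s\t%d\t%d", outl$scaffold, outl$start - 1L, outl$end),
    file.path(out_dir, "outlier_windows.bed")
  )
  paths_out$outlier_bed <- file.path(out_dir, "outlier_windows.bed")
  if (!is.null(pca_all)) {
    sc <- data.frame(sample = rownames(pca_all$scores), pca_all$scores[, 1:4])
    paths_out$pca <- tsv(sc, "pca_scores.tsv")
    jsonlite::write_json(
      lapply(inversions, function(x) x[c(
        "scaffold", "detected", "reason", "cluster_sizes", "separation",
        "cluster_het", "ld_scaffold", "ld_background", "ld_compare"
      )]),
      file.path(out_dir, "inversions.json"), auto_unbox = TRUE, digits = 6,
      na = "null"
    )
    paths_out$inversions <- file.path(out_dir, "inversions.json")
  }
  log_lines <- c(
    sprintf("migrascan %s", as.character(utils::packageVersion("migrascan"))),
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s", config$mode),
    sprintf("samples retained: %d", nrow(gm$samples)),
    sprintf("sites retained: %d", ncol(gm$geno)),
    sprintf("individuals removed (low depth): %s",
            paste(fc$removed_individuals, collapse = ", ")),
    sprintf("individuals removed (relatedness): %s",
            paste(related_removed, collapse = ", ")),
    sprintf("outlier threshold (delta-FST'): %.6f", attr(windows, "threshold")),
    sprintf("clusters called: %d", nrow(clusters))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths_out$log <- file.path(out_dir, "run_log.txt")

  invisible(list(
    gm = gm, windows = windows, clusters = clusters, kinship = kin,
    removed_low_depth = fc$removed_individuals,
    removed_related = related_removed,
    pca_all = pca_all, pca_focal = pca_focal, inversions = inversions,
    filter_report = fc$report, paths = paths_out, config = config
  ))
}
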