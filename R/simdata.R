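#' Simulation configuration for a synthetic resequencing cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate the study design the scan machinery is aimed at: four
#' structured populations (9/7/24/9 diploids) drawn from a shared ancestral
#' pool under the Balding-Nichols model, a panmictic focal population split
#' into two phenotype groups of 12, a growth-skewed (singleton-enriched)
#' site-frequency spectrum, one planted 50 kb region of elevated
#' between-phenotype differentiation, and an inversion polymorphism
#' segregating in two populations only.
#'
#' @param seed integer seed; all draws flow from this single generator.
#' @param scaffolds data.frame with columns `name`, `length` (bp),
#'   `chromosome` (label used only for reporting).
#' @param n_sites_per_scaffold SNV count per scaffold: a scalar (recycled)
#'   or one count per scaffold; `NULL` derives counts from `snv_per_kb`.
#' @param snv_per_kb SNV density used when `n_sites_per_scaffold` is
#'   `NULL` (default 20/kb, the density of a deeply filtered songbird
#'   resequencing call set).
#' @param populations data.frame with columns `name`, `n` (diploid
#'   individuals) and `F` (Balding-Nichols divergence from the ancestral
#'   pool, in `[0,1)`).
#' @param focal_population population whose individuals are split into two
#'   phenotype groups.
#' @param phenotypes length-2 character vector of group labels for the
#'   focal population (split as evenly as possible, first label first).
#' @param selected_region `NULL` or list(scaffold, start, end, delta,
#'   group): allele-frequency shift `delta` applied to one phenotype
#'   group's sampling frequencies inside the region (clipped to
#'   `[0.02, 0.98]`).
#' @param inversion `NULL` or list(scaffold, start, end, carriers, q): an
#'   inversion haplotype at frequency `q` (Hardy-Weinberg draw) in the
#'   carrier populations; marker sites inside the block are in perfect LD
#'   before missingness.
#' @param sfs_skew singleton-excess multiplier (>= 1) applied to the
#'   lowest-frequency class of the ancestral spectrum; 1 = neutral 1/i SFS.
#' @param missing_rate probability a genotype call is missing outright.
#' @param depth_model list(mean, low_fraction): mean per-individual read
#'   depth and the fraction of individuals simulated at low depth (below
#'   half the cohort mean, so the depth filter removes them).
#' @param repeat_fraction fraction of each scaffold covered by simulated
#'   repeat intervals.
#' @param related_pairs number of parent-offspring pairs appended to the
#'   cohort after the base draw.
#' @param site_fail_rate per-rule fraction of sites drawn to fail each of
#'   the QUAL / site-DP / MQ / RPBZ filters.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scaffolds = data.frame(
                         name = paste0("scaffold_", 1:5),
                         length = c(5e5, 5e5, 2e6, 1e6, 1e6),
                         chromosome = c("chr1", "chr2", "chr9", "chr9", "chr3")
                       ),
                       n_sites_per_scaffold = NULL,
                       snv_per_kb = 20,
                       populations = data.frame(
                         name = c("spain", "france", "germany", "russia"),
                         n = c(9L, 7L, 24L, 9L),
                         F = c(0.06, 0.02, 0.005, 0.005)
                       ),
                       focal_population = "germany",
                       phenotypes = c("migratory", "resident"),
                       selected_region = list(
                         scaffold = "scaffold_3", start = 500001, end = 550000,
                         delta = 0.35, group = "migratory"
                       ),
                       inversion = list(
                         scaffold = "scaffold_4", start = 200001, end = 700000,
                         carriers = c("spain", "france"), q = 0.5
                       ),
                       sfs_skew = 8,
                       missing_rate = 0.02,
                       depth_model = list(mean = 15, low_fraction = 0),
                       repeat_fraction = 0.05,
                       related_pairs = 0L,
                       site_fail_rate = 0.02) {
  if (is.null(n_sites_per_scaffold)) {
    n_sites_per_scaffold <- round(snv_per_kb * scaffolds$length / 1000)
  }
  n_sites_per_scaffold <- rep_len(as.integer(n_sites_per_scaffold),
                                  nrow(scaffolds))
  cfg <- list(
    seed = as.integer(seed), scaffolds = scaffolds,
    n_sites_per_scaffold = n_sites_per_scaffold,
    populations = populations, focal_population = focal_population,
    phenotypes = phenotypes, selected_region = selected_region,
    inversion = inversion, sfs_skew = sfs_skew, missing_rate = missing_rate,
    depth_model = depth_model, repeat_fraction = repeat_fraction,
    related_pairs = as.integer(related_pairs), site_fail_rate = site_fail_rate
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  F <- cfg$populations$F
  if (any(!is.finite(F)) || any(F < 0) || any(F >= 1)) {
    stop("population divergence F must be finite and in [0, 1)")
  }
  if (cfg$sfs_skew < 1) stop("sfs_skew must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction >= 1) stop("repeat_fraction must be in [0, 1)")
  if (!cfg$focal_population %in% cfg$populations$name) {
    stop("focal_population not among population names")
  }
  in_scaffold <- function(reg) {
    i <- match(reg$scaffold, cfg$scaffolds$name)
    !is.na(i) && reg$start >= 1 && reg$end <= cfg$scaffolds$length[i] && reg$start <= reg$end
  }
  if (!is.null(cfg$selected_region)) {
    if (!in_scaffold(cfg$selected_region)) stop("selected_region outside scaffold bounds")
    d <- cfg$selected_region$delta
    if (d < 0 || d > 1) stop("selected_region delta must be in [0, 1]")
  }
  if (!is.null(cfg$inversion)) {
    if (!in_scaffold(cfg$inversion)) stop("inversion outside scaffold bounds")
    if (cfg$inversion$q <= 0 || cfg$inversion$q >= 1) stop("inversion frequency q must be in (0, 1)")
  }
  if (!is.null(cfg$selected_region) && !is.null(cfg$inversion) &&
      identical(cfg$selected_region$scaffold, cfg$inversion$scaffold)) {
    a <- cfg$selected_region; b <- cfg$inversion
    if (a$start <= b$end && b$start <= a$end) {
      stop("selected_region and inversion must not overlap")
    }
  }
  invisible(cfg)
}

# Ancestral spectrum: a 99-point grid p = i/100 (so frequencies live in
# [0.01, 0.99]) with neutral weights 1/i; sfs_skew multiplies the weight of
# the lowest class, producing the singleton excess expected under
# population growth.
sfs_grid <- function(sfs_skew) {
  p <- (1:99) / 100
  w <- 1 / (1:99)
  w[1] <- w[1] * sfs_skew
  list(p = p, w = w / sum(w))
}

#' Draw structured per-population allele frequencies
#'
#' Ancestral frequencies are drawn from a singleton-weighted 1/i spectrum
#' restricted to `[0.01, 0.99]`; each population's frequencies are then
#' Balding-Nichols draws: Beta with mean `p` and variance `F p (1 - p)`.
#' `F = 0` returns the ancestral frequency unchanged.
#'
#' @param config a [sim_config()].
#' @param n_sites total number of sites to draw (defaults to scaffolds x
#'   `n_sites_per_scaffold`).
#' @return list with `ancestral` (numeric vector) and `pop_freq` (matrix,
#'   populations x sites, rownames = population names).
#' @export
draw_structured_frequencies <- function(config, n_sites = NULL) {
  validate_sim_config(config)
  if (is.null(n_sites)) {
    n_sites <- sum(rep_len(config$n_sites_per_scaffold, nrow(config$scaffolds)))
  }
  grid <- sfs_grid(config$sfs_skew)
  anc <- sample(grid$p, n_sites, replace = TRUE, prob = grid$w)
  pops <- config$populations
  pf <- matrix(NA_real_, nrow(pops), n_sites, dimnames = list(pops$name, NULL))
  for (i in seq_len(nrow(pops))) {
    F <- pops$F[i]
    if (F == 0) {
      pf[i, ] <- anc
    } else {
      k <- (1 - F) / F
      pf[i, ] <- stats::rbeta(n_sites, anc * k, (1 - anc) * k)
    }
  }
  list(ancestral = anc, pop_freq = pf)
}

#' Simulate a full synthetic cohort
#'
#' Draws structured allele frequencies, samples diploid genotypes per
#' population, plants the configured selected region and inversion, applies
#' random genotype missingness, simulates site-level QC annotations
#' (QUAL/DP/MQ/RPBZ, with a configurable fraction of sites failing each
#' rule), per-sample read depths, repeat intervals, and appends the
#' configured related pairs.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements `gm` (a
#'   [genotype_matrix()]), `truth` (selected-region coordinates, inversion
#'   genotypes, pedigree, per-population allele frequencies, repeat
#'   intervals) and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  scf <- config$scaffolds
  m_per <- rep_len(config$n_sites_per_scaffold, nrow(scf))
  sites <- do.call(rbind, lapply(seq_len(nrow(scf)), function(i) {
    data.frame(
      scaffold = scf$name[i],
      pos = sort(sample.int(scf$length[i], m_per[i])),
      stringsAsFactors = FALSE
    )
  }))
  m <- nrow(sites)
  freqs <- draw_structured_frequencies(config, n_sites = m)

  pops <- config$populations
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(
      sample = sprintf("%s_%02d", pops$name[i], seq_len(pops$n[i])),
      population = pops$name[i], phenotype = "none",
      stringsAsFactors = FALSE
    )
  }))
  focal <- samples$population == config$focal_population
  nf <- sum(focal)
  samples$phenotype[focal] <- rep(config$phenotypes, c(ceiling(nf / 2), floor(nf / 2)))

  n_ind <- nrow(samples)
  geno <- matrix(NA_integer_, n_ind, m)
  for (pop in pops$name) {
    rows <- which(samples$population == pop)
    p <- freqs$pop_freq[pop, ]
    draws <- stats::rbinom(length(rows) * m, 2L, rep(p, each = length(rows)))
    geno[rows, ] <- matrix(draws, length(rows), m)
  }

  # read depths: low-depth individuals sit well under half the cohort mean
  dm <- config$depth_model
  ind_depth <- round(stats::rnorm(n_ind, dm$mean, dm$mean * 0.1), 2)
  ind_depth <- pmax(ind_depth, dm$mean * 0.6)
  n_low <- round(dm$low_fraction * n_ind)
  low_idx <- integer()
  if (n_low > 0) {
    low_idx <- sample.int(n_ind, n_low)
    ind_depth[low_idx] <- round(stats::runif(n_low, 0.15, 0.4) * dm$mean, 2)
  }
  samples$mean_depth <- ind_depth
  dp <- matrix(
    stats::rpois(n_ind * m, rep(ind_depth, times = m)), n_ind, m
  )

  # site QC annotations: most records pass; site_fail_rate of sites fail
  # each rule (drawn independently per rule)
  fr <- config$site_fail_rate
  qual <- round(stats::runif(m, 30, 900), 1)
  fail <- stats::runif(m) < fr
  qual[fail] <- round(stats::runif(sum(fail), 2, 20), 1)
  mq <- round(stats::runif(m, 40, 60), 1)
  fail <- stats::runif(m) < fr
  mq[fail] <- round(stats::runif(sum(fail), 10, 30), 1)
  rpbz <- round(pmax(-3, pmin(3, stats::rnorm(m))), 3)
  fail <- stats::runif(m) < fr
  rpbz[fail] <- round(sample(c(-1, 1), sum(fail), TRUE) * stats::runif(sum(fail), 3.1, 6), 3)
  info_mean <- n_ind * dm$mean
  info_dp <- round(pmin(pmax(stats::rnorm(m, info_mean, info_mean * 0.1),
                              n_ind + 1), 1.7 * info_mean))
  fail <- stats::runif(m) < fr / 2
  info_dp[fail] <- sample.int(n_ind, sum(fail), replace = TRUE)
  fail <- stats::runif(m) < fr / 2
  info_dp[fail] <- round(info_mean * stats::runif(sum(fail), 2.5, 3.5))

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")

  site_tab <- cbind(sites, data.frame(
    ref = ref, alt = unname(alt), qual = qual, dp = as.integer(info_dp),
    mq = mq, rpbz = rpbz, stringsAsFactors = FALSE
  ))
  gm <- genotype_matrix(geno, site_tab, samples, dp = dp)

  cohort <- structure(
    list(
      gm = gm, config = config,
      truth = list(
        pop_freq = freqs$pop_freq, ancestral = freqs$ancestral,
        selected_region = NULL, inversion_genotype = NULL,
        low_depth_ids = samples$sample[low_idx],
        pedigree = data.frame(
          parent = character(), offspring = character(), relation = character(),
          stringsAsFactors = FALSE
        ),
        repeats = sim_repeats(config)
      )
    ),
    class = "sim_cohort"
  )

  if (!is.null(config$selected_region) && config$selected_region$delta > 0) {
    cohort <- plant_selected_region(cohort, config$selected_region)
  }
  if (!is.null(config$inversion)) {
    cohort <- plant_inversion(cohort, config$inversion)
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n_ind * m) < config$missing_rate, n_ind, m)
    cohort$gm$geno[drop] <- NA_integer_
  }
  for (k in seq_len(config$related_pairs)) {
    parent <- sample(cohort$gm$samples$sample, 1)
    cohort <- append_related_pair(cohort, parent)
  }
  cohort
}

# Random repeat intervals (0-based half-open) covering ~repeat_fraction of
# each scaffold, merged with IRanges::reduce.
sim_repeats <- function(config) {
  out <- lapply(seq_len(nrow(config$scaffolds)), function(i) {
    len <- config$scaffolds$length[i]
    k <- round(config$repeat_fraction * len / 2000)
    if (k == 0) return(NULL)
    s <- sort(sample.int(len - 2000L, k))
    ir <- IRanges::reduce(IRanges::IRanges(start = s, width = 2000L))
    data.frame(
      scaffold = config$scaffolds$name[i],
      start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(), start = integer(), end = integer())
  }
  out
}

#' Plant a region of elevated between-phenotype differentiation
#'
#' Redraws the genotypes of one phenotype group at every site inside the
#' region from a shifted allele frequency `clip(p + delta, 0.02, 0.98)`,
#' where `p` is the group's population frequency. `delta = 0` leaves the
#' distribution unchanged (the draws are refreshed).
#'
#' @param cohort a `sim_cohort`.
#' @param region list(scaffold, start, end, delta, group).
#' @return The cohort with shifted genotypes and an updated truth record.
#' @export
plant_selected_region <- function(cohort, region) {
  scf <- cohort$config$scaffolds
  i <- match(region$scaffold, scf$name)
  if (is.na(i) || region$start < 1 || region$end > scf$length[i]) {
    stop("selected region outside scaffold bounds")
  }
  gm <- cohort$gm
  in_reg <- gm$sites$scaffold == region$scaffold &
    gm$sites$pos >= region$start & gm$sites$pos <= region$end
  ids <- gm$samples$phenotype == region$group
  if (any(in_reg) && any(ids)) {
    pop <- cohort$config$focal_population
    p <- pmin(pmax(cohort$truth$pop_freq[pop, in_reg] + region$delta, 0.02), 0.98)
    nr <- sum(ids)
    gm$geno[ids, in_reg] <- matrix(
      stats::rbinom(nr * length(p), 2L, rep(p, each = nr)), nr, length(p)
    )
    cohort$truth$shifted_freq <- p
  }
  cohort$gm <- gm
  cohort$truth$selected_region <- region
  cohort
}

#' Plant an inversion polymorphism
#'
#' Each individual in a carrier population receives an inversion genotype
#' by a Hardy-Weinberg draw at haplotype frequency `q`; all other
#' individuals are homozygous standard. Every marker site inside the block
#' is overwritten with the inversion dosage (0/1/2), so the block is in
#' perfect LD until missingness degrades it.
#'
#' @param cohort a `sim_cohort`.
#' @param inversion list(scaffold, start, end, carriers, q).
#' @return The cohort with the block planted and truth updated.
#' @export
plant_inversion <- function(cohort, inversion) {
  if (inversion$q <= 0 || inversion$q >= 1) stop("inversion frequency q must be in (0, 1)")
  gm <- cohort$gm
  in_blk <- gm$sites$scaffold == inversion$scaffold &
    gm$sites$pos >= inversion$start & gm$sites$pos <= inversion$end
  inv_gt <- integer(nrow(gm$samples))
  carrier <- gm$samples$population %in% inversion$carriers
  inv_gt[carrier] <- stats::rbinom(sum(carrier), 2L, inversion$q)
  if (any(in_blk)) {
    gm$geno[, in_blk] <- matrix(inv_gt, nrow(gm$geno), sum(in_blk))
  }
  names(inv_gt) <- gm$samples$sample
  cohort$gm <- gm
  cohort$truth$inversion <- inversion
  cohort$truth$inversion_genotype <- inv_gt
  cohort
}

#' Append a related individual to the cohort
#'
#' In `"offspring"` mode the new individual receives, at each site, one
#' allele transmitted uniformly from the parent and one drawn from the
#' parent's population allele frequency (expected Method-of-Moments kinship
#' 0.25); `"clone"` duplicates the parent's genotypes (expected kinship
#' 0.5). The new individual is given a lower simulated mean depth than the
#' parent so the lower-depth-member exclusion rule resolves
#' deterministically.
#'
#' @param cohort a `sim_cohort`.
#' @param parent_id sample id of the existing parent.
#' @param mode `"offspring"` or `"clone"`.
#' @return The cohort with one more sample and the pedigree updated.
#' @export
append_related_pair <- function(cohort, parent_id, mode = c("offspring", "clone")) {
  mode <- match.arg(mode)
  gm <- cohort$gm
  pi <- match(parent_id, gm$samples$sample)
  if (is.na(pi)) stop("unknown parent id: ", parent_id)
  m <- ncol(gm$geno)
  pop <- gm$samples$population[pi]
  p <- cohort$truth$pop_freq[pop, ]
  pg <- gm$geno[pi, ]
  if (mode == "clone") {
    child <- pg
  } else {
    transmitted <- ifelse(
      is.na(pg), stats::rbinom(m, 1L, p),
      ifelse(pg == 1L, stats::rbinom(m, 1L, 0.5), as.integer(pg / 2L))
    )
    child <- as.integer(transmitted + stats::rbinom(m, 1L, p))
    # inversion markers are inherited as a haplotype, not per-site
    if (!is.null(cohort$truth$inversion_genotype)) {
      inv <- cohort$truth$inversion
      in_blk <- gm$sites$scaffold == inv$scaffold &
        gm$sites$pos >= inv$start & gm$sites$pos <= inv$end
      if (any(in_blk)) {
        pg_inv <- cohort$truth$inversion_genotype[[parent_id]]
        tr <- if (pg_inv == 1L) stats::rbinom(1, 1L, 0.5) else pg_inv / 2L
        other <- if (pop %in% inv$carriers) stats::rbinom(1, 1L, inv$q) else 0L
        child[in_blk] <- as.integer(tr + other)
      }
    }
  }
  child_id <- sprintf("%s_%s%d", parent_id, substr(mode, 1, 3),
                      nrow(cohort$truth$pedigree) + 1L)
  depth <- round(gm$samples$mean_depth[pi] * 0.75, 2)
  new_samples <- rbind(gm$samples, data.frame(
    sample = child_id, population = pop,
    phenotype = gm$samples$phenotype[pi], mean_depth = depth,
    stringsAsFactors = FALSE
  ))
  new_dp <- if (!is.null(gm$dp)) {
    rbind(gm$dp, stats::rpois(m, depth))
  }
  cohort$gm <- genotype_matrix(
    rbind(gm$geno, child), gm$sites, new_samples, dp = new_dp
  )
  cohort$truth$pedigree <- rbind(cohort$truth$pedigree, data.frame(
    parent = parent_id, offspring = child_id,
    relation = if (mode == "clone") "duplicate" else "parent_offspring",
    stringsAsFactors = FALSE
  ))
  if (!is.null(cohort$truth$inversion_genotype)) {
    ig <- cohort$truth$inversion_genotype
    newg <- if (mode == "clone") ig[[parent_id]] else NA_integer_
    cohort$truth$inversion_genotype <- c(ig, stats::setNames(newg, child_id))
  }
  cohort
}

#' Write a simulated cohort to disk
#'
#' Emits an uncompressed VCF v4.2 (QUAL; INFO DP, MQ, RPBZ; FORMAT GT:DP),
#' a BED of repeat intervals (0-based half-open), a tab-separated sample
#' sheet (`sample  population  phenotype  mean_depth`) and a JSON truth
#' sidecar. Output is deterministic: the same cohort always produces
#' byte-identical files.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- cohort$gm
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    bed = file.path(dir, paste0(prefix, "_repeats.bed")),
    samples = file.path(dir, paste0(prefix, "_samples.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  scf <- cohort$config$scaffolds
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=migrascan_simdata",
    sprintf("##contig=<ID=%s,length=%d>", scf$name, as.integer(scf$length)),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Raw read depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Average mapping quality">',
    '##INFO=<ID=RPBZ,Number=1,Type=Float,Description="Read position bias Z-score">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Per-sample read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[as.character(gm$geno[ok])]
  dp <- if (!is.null(gm$dp)) gm$dp else matrix(".", nrow(gm$geno), ncol(gm$geno))
  cells <- matrix(paste(gt, dp, sep = ":"), nrow(gm$geno))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;MQ=%s;RPBZ=%s\tGT:DP\t%s",
    gm$sites$scaffold, gm$sites$pos, gm$sites$ref, gm$sites$alt,
    format_num(gm$sites$qual), gm$sites$dp, format_num(gm$sites$mq),
    format_num(gm$sites$rpbz),
    apply(cells, 2, paste, collapse = "\t")
  )
  writeLines(c(hdr, body), paths$vcf)

  reps <- cohort$truth$repeats
  if (nrow(reps)) {
    writeLines(sprintf("%s\t%d\t%d", reps$scaffold, reps$start, reps$end), paths$bed)
  } else {
    file.create(paths$bed)
  }
  utils::write.table(gm$samples, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  truth$pop_freq <- NULL  # bulky; kept in memory only
  truth$ancestral <- NULL
  truth$shifted_freq <- NULL
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  sub("\\.$", "", trimws(out))
}
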