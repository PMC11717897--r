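#' Flag outlier windows on delta-FST'
#'
#' The threshold is the genome-wide 99th percentile (linear-interpolation
#' quantile) of the non-missing `delta_fst_prime` values; windows strictly
#' above it are outliers. Missing windows keep a missing flag.
#'
#' @param windows window table with `delta_fst_prime` (see
#'   [delta_fst_prime()]).
#' @param percentile outlier percentile (default 99).
#' @return The table with a `flag` column: `"outlier"`, `"background"` or
#'   `NA` (missing), plus the threshold as attribute `"threshold"`.
#' @export
call_outliers <- function(windows, percentile = 99) {
  v <- windows$delta_fst_prime
  ok <- !is.na(v)
  if (!any(ok)) stop("all windows missing; cannot set an outlier threshold")
  thr <- stats::quantile(v[ok], percentile / 100, type = 7, names = FALSE)
  windows$flag <- ifelse(ok, ifelse(v > thr, "outlier", "background"), NA)
  attr(windows, "threshold") <- thr
  windows
}

#' Call outlier clusters from per-window flags
#'
#' A cluster is a maximal run of at least `min_windows` outlier windows on
#' one scaffold's window grid, where missing windows are skipped (they
#' neither break the run nor count toward its length) and background
#' windows break runs. Clusters never span scaffolds.
#'
#' @param flags character vector over `{"outlier", "background", NA}` in
#'   window order.
#' @param scaffold scaffold label per window (default: one scaffold).
#' @param min_windows minimum outlier windows per cluster (default 5).
#' @return Integer vector of cluster ids (`NA` for windows in no cluster);
#'   only outlier windows are cluster members. Ids number clusters in
#'   genome order starting at 1.
#' @export
call_clusters <- function(flags, scaffold = NULL, min_windows = 5) {
  n <- length(flags)
  if (is.null(scaffold)) scaffold <- rep("", n)
  out <- rep(NA_integer_, n)
  nid <- 0L
  for (s in unique(scaffold)) {
    idx <- which(scaffold == s)
    f <- flags[idx]
    keep <- which(!is.na(f))      # skip missing windows entirely
    if (!length(keep)) next
    r <- rle(f[keep] == "outlier")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] >= min_windows) {
        nid <- nid + 1L
        out[idx[keep[starts[j]:ends[j]]]] <- nid
      }
    }
  }
  out
}

#' Summarize outlier clusters (scan report table)
#'
#' One row per cluster: outlier-window count, mean delta-FST', mean and
#' median window FST, and mean Tajima's D per phenotype group over the
#' member windows (medians use the midpoint convention for even counts).
#'
#' @param windows window table carrying `delta_fst_prime`, `fst`,
#'   `tajima_d1`, `tajima_d2` and optionally a `chromosome` column.
#' @param cluster integer cluster ids as returned by [call_clusters()].
#' @return data.frame with one row per cluster: `cluster_id`, `scaffold`,
#'   `start`, `end`, `n_windows`, `mean_delta_fst_prime`, `mean_fst`,
#'   `median_fst`, `mean_tajima_d1`, `mean_tajima_d2`, `chromosome`.
#' @export
summarize_clusters <- function(windows, cluster) {
  ids <- sort(unique(cluster[!is.na(cluster)]))
  rows <- lapply(ids, function(k) {
    w <- windows[which(cluster == k), , drop = FALSE]
    data.frame(
      cluster_id = sprintf("%s_cluster%d", w$scaffold[1], k),
      scaffold = w$scaffold[1],
      start = min(w$start), end = max(w$end),
      n_windows = nrow(w),
      mean_delta_fst_prime = mean(w$delta_fst_prime),
      mean_fst = mean(w$fst),
      median_fst = stats::median(w$fst),
      mean_tajima_d1 = mean(w$tajima_d1, na.rm = TRUE),
      mean_tajima_d2 = mean(w$tajima_d2, na.rm = TRUE),
      chromosome = if ("chromosome" %in% names(w)) w$chromosome[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      cluster_id = character(), scaffold = character(), start = integer(),
      end = integer(), n_windows = integer(), mean_delta_fst_prime = numeric(),
      mean_fst = numeric(), median_fst = numeric(), mean_tajima_d1 = numeric(),
      mean_tajima_d2 = numeric(), chromosome = character(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Outlier windows shared between two comparisons
#'
#' Windows flagged as outliers in both comparisons (matched on the same
#' (scaffold, start) grid), and which of the shared windows fall inside an
#' outlier cluster of either comparison.
#'
#' @param a,b window tables with `flag` columns from [call_outliers()],
#'   on identical grids.
#' @param cluster_a,cluster_b optional cluster-id vectors from
#'   [call_clusters()] for each comparison.
#' @return list with `n_shared`, the shared-window table, and
#'   `n_in_clusters` (shared windows inside a cluster of either side).
#' @export
shared_outlier_windows <- function(a, b, cluster_a = NULL, cluster_b = NULL) {
  if (nrow(a) != nrow(b) || !identical(a$scaffold, b$scaffold) ||
      !identical(a$start, b$start)) {
    stop("window grids of the two comparisons do not match")
  }
  shared <- !is.na(a$flag) & !is.na(b$flag) & a$flag == "outlier" & b$flag == "outlier"
  in_cl <- rep(FALSE, nrow(a))
  if (!is.null(cluster_a)) in_cl <- in_cl | !is.na(cluster_a)
  if (!is.null(cluster_b)) in_cl <- in_cl | !is.na(cluster_b)
  list(
    n_shared = sum(shared),
    windows = a[shared, c("scaffold", "start", "end"), drop = FALSE],
    n_in_clusters = sum(shared & in_cl)
  )
}

#' Compare Tajima's D in cluster windows with the genome-wide background
#'
#' Kruskal-Wallis rank test of the member windows' D against all
#' genome-wide window D values, for one phenotype group. Raw (uncorrected)
#' p-values are reported. All-tied input yields H = 0 and p = 1 with a
#' warning.
#'
#' @param cluster_d numeric D values of the cluster's member windows.
#' @param genome_d numeric genome-wide window D values.
#' @return list(statistic, p_value, n_cluster, n_genome).
#' @export
compare_cluster_tajimas_d <- function(cluster_d, genome_d) {
  cluster_d <- cluster_d[!is.na(cluster_d)]
  genome_d <- genome_d[!is.na(genome_d)]
  if (length(cluster_d) < 2 || length(genome_d) < 2) {
    stop("need at least two non-missing values per side")
  }
  vals <- c(cluster_d, genome_d)
  if (length(unique(vals)) == 1) {
    warning("all values tied; reporting p = 1")
    return(list(statistic = 0, p_value = 1,
                n_cluster = length(cluster_d), n_genome = length(genome_d)))
  }
  kt <- stats::kruskal.test(
    vals, factor(rep(c("cluster", "genome"), c(length(cluster_d), length(genome_d))))
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_cluster = length(cluster_d), n_genome = length(genome_d))
}

#' Genotype-class tallies in a candidate region
#'
#' For one group of samples and all sites inside a region, reports (i) raw
#' genotype tallies summed over sites (`het_genotypes`,
#' `hom_alt_genotypes`) and (ii) counts of sites whose modal (majority)
#' genotype class in the group is heterozygous or homozygous-alternative
#' (`het_sites`, `hom_alt_sites`). Both conventions are returned because
#' either may be wanted when describing a differentiated haplotype.
#'
#' @param gm a [genotype_matrix()].
#' @param scaffold,start,end region coordinates (1-based inclusive).
#' @param group character vector of sample ids.
#' @return list(het_genotypes, hom_alt_genotypes, het_sites,
#'   hom_alt_sites, n_sites).
#' @export
genotype_class_counts <- function(gm, scaffold, start, end, group) {
  sel <- gm$sites$scaffold == scaffold & gm$sites$pos >= start & gm$sites$pos <= end
  if (!any(sel)) {
    return(list(het_genotypes = 0L, hom_alt_genotypes = 0L,
                het_sites = 0L, hom_alt_sites = 0L, n_sites = 0L))
  }
  g <- gm$geno[match(group, gm$samples$sample), sel, drop = FALSE]
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  modal <- max.col(cbind(n0, n1, n2), ties.method = "first")
  list(
    het_genotypes = sum(n1),
    hom_alt_genotypes = sum(n2),
    het_sites = sum(modal == 2L & n1 > 0L),
    hom_alt_sites = sum(modal == 3L & n2 > 0L),
    n_sites = sum(sel)
  )
}

#' Scaffold FST fold-enrichment
#'
#' Mean non-missing window FST on one scaffold divided by the genome-wide
#' mean (and optionally by another scaffold's mean).
#'
#' @param windows window table with `scaffold` and `fst`.
#' @param scaffold focal scaffold name.
#' @param other optional second scaffold for a scaffold-vs-scaffold ratio.
#' @return list(fold_genome, fold_other, scaffold_mean, genome_mean).
#' @export
scaffold_fold_enrichment <- function(windows, scaffold, other = NULL) {
  ok <- !is.na(windows$fst)
  sm <- mean(windows$fst[ok & windows$scaffold == scaffold])
  gm_mean <- mean(windows$fst[ok])
  fold <- if (is.nan(gm_mean) || gm_mean == 0) NA_real_ else sm / gm_mean
  fold_other <- NA_real_
  if (!is.null(other)) {
    om <- mean(windows$fst[ok & windows$scaffold == other])
    fold_other <- if (is.nan(om) || om == 0) NA_real_ else sm / om
  }
  list(fold_genome = fold, fold_other = fold_other,
       scaffold_mean = sm, genome_mean = gm_mean)
}
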