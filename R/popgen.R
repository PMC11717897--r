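#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 p (1 - p) n / (n - 1)` from the
#' alt-allele frequency `p` and the number of non-missing allele copies
#' `n`. Sites with fewer than two copies return `NA`.
#'
#' @param p alt-allele frequency (vectorized).
#' @param n non-missing allele-copy count (vectorized).
#' @return Numeric vector of per-site pi.
#' @export
site_pi <- function(p, n) {
  ifelse(!is.na(p) & n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
}

#' Per-site between-group divergence Dxy
#'
#' `p1 (1 - p2) + p2 (1 - p1)`: the probability two allele copies, one
#' from each group, differ. `NA` if either frequency is undefined.
#'
#' @param p1,p2 alt-allele frequencies in the two groups (vectorized).
#' @return Numeric vector of per-site Dxy.
#' @export
site_dxy <- function(p1, p2) {
  ifelse(is.na(p1) | is.na(p2), NA_real_, p1 * (1 - p2) + p2 * (1 - p1))
}

# 1-based tiling windows of `size` bp starting at position 1: position P
# falls in window floor((P - 1) / size), covering [size*k + 1, size*(k+1)].
window_index <- function(pos, size = 2500) {
  as.integer((pos - 1) %/% size)
}

#' Windowed Hudson FST, pi and Dxy plus Tajima's D for two groups
#'
#' Tiles each scaffold from position 1 in non-overlapping windows and
#' computes, over the variant sites with defined allele frequencies in
#' both groups, the per-site means of within-group pi and between-group
#' Dxy, the Hudson ratio-of-averages estimator
#' `FST = 1 - ((pi1 + pi2) / 2) / Dxy`, and Tajima's D within each group.
#' A window is flagged missing when it holds fewer than `min_snvs` usable
#' sites or its mean Dxy is zero; negative FST values are retained.
#'
#' @param gm a [genotype_matrix()].
#' @param group1,group2 character vectors of sample ids.
#' @param window_size window width in bp (default 2500).
#' @param min_snvs minimum usable SNVs per window (default 10).
#' @return data.frame with one row per window that contains at least one
#'   site: `scaffold`, `start`, `end` (1-based inclusive), `n_snvs`,
#'   `pi1`, `pi2`, `dxy`, `fst`, `tajima_d1`, `tajima_d2`, `missing`.
#' @export
window_stats <- function(gm, group1, group2, window_size = 2500, min_snvs = 10) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  f1 <- group_freq(gm, group1)
  f2 <- group_freq(gm, group2)
  pi1 <- site_pi(f1$p, f1$n)
  pi2 <- site_pi(f2$p, f2$n)
  dxy <- site_dxy(f1$p, f2$p)
  usable <- !is.na(pi1) & !is.na(pi2) & !is.na(dxy)

  n1 <- 2L * length(group1)
  n2 <- 2L * length(group2)
  # segregating within a group needs only that group's data
  seg1 <- !is.na(pi1) & f1$p > 0 & f1$p < 1
  seg2 <- !is.na(pi2) & f2$p > 0 & f2$p < 1
  seg1[is.na(seg1)] <- FALSE
  seg2[is.na(seg2)] <- FALSE

  dt <- data.table::data.table(
    scaffold = gm$sites$scaffold,
    win = window_index(gm$sites$pos, window_size),
    usable = usable,
    pi1 = ifelse(usable, pi1, 0), pi2 = ifelse(usable, pi2, 0),
    dxy = ifelse(usable, dxy, 0),
    seg1 = seg1, seg2 = seg2,
    pis1 = ifelse(seg1, pi1, 0), pis2 = ifelse(seg2, pi2, 0)
  )
  agg <- dt[, list(
    n_snvs = sum(usable),
    pi1 = sum(pi1), pi2 = sum(pi2), dxy = sum(dxy),
    S1 = sum(seg1), S2 = sum(seg2),
    pi_sum1 = sum(pis1), pi_sum2 = sum(pis2)
  ), by = c("scaffold", "win")]
  data.table::setorderv(agg, c("scaffold", "win"))

  n_snvs <- agg$n_snvs
  pi1w <- ifelse(n_snvs > 0, agg$pi1 / n_snvs, NA_real_)
  pi2w <- ifelse(n_snvs > 0, agg$pi2 / n_snvs, NA_real_)
  dxyw <- ifelse(n_snvs > 0, agg$dxy / n_snvs, NA_real_)
  fst <- ifelse(!is.na(dxyw) & dxyw > 0, 1 - ((pi1w + pi2w) / 2) / dxyw, NA_real_)
  miss <- n_snvs < min_snvs | is.na(dxyw) | dxyw == 0

  out <- data.frame(
    scaffold = agg$scaffold,
    start = agg$win * window_size + 1L,
    end = (agg$win + 1L) * window_size,
    n_snvs = n_snvs,
    pi1 = pi1w, pi2 = pi2w, dxy = dxyw,
    fst = ifelse(miss, NA_real_, fst),
    tajima_d1 = tajima_d(agg$S1, agg$pi_sum1, n1),
    tajima_d2 = tajima_d(agg$S2, agg$pi_sum2, n2),
    missing = miss,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Tajima constants for a sample of n sequences.
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from segregating sites and summed pairwise diversity
#'
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' Watterson constants for `n` sequences. `S = 0` returns `NA`.
#'
#' @param S number of segregating sites (vectorized).
#' @param pi_sum sum of per-site pairwise diversity over those sites
#'   (vectorized).
#' @param n nominal number of sequences (2 x diploid individuals).
#' @return Numeric vector of D values.
#' @export
tajima_d <- function(S, pi_sum, n) {
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  ifelse(S > 0, (pi_sum - S / k$a1) / denom, NA_real_)
}

#' Per-SNV Weir & Cockerham FST
#'
#' The 1984 variance-components estimator for two groups: among-population
#' (a), among-individual (b) and within-individual (c) components from the
#' group allele frequencies, sample sizes and observed heterozygote
#' proportions; `theta = a / (a + b + c)`. Negative estimates are
#' retained; monomorphic sites (`a + b + c = 0`) return `NA`. Sites with
#' fewer than two non-missing individuals in either group return `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param group1,group2 character vectors of sample ids.
#' @return data.frame with `scaffold`, `pos`, `p1`, `p2`, `n1`, `n2`
#'   (individuals), `a`, `b`, `c`, `theta`.
#' @export
per_snv_fst_wc <- function(gm, group1, group2) {
  f1 <- group_freq(gm, group1)
  f2 <- group_freq(gm, group2)
  h1 <- group_het(gm, group1)
  h2 <- group_het(gm, group2)
  n1 <- f1$n / 2  # diploid individuals with non-missing genotypes
  n2 <- f2$n / 2
  comp <- wc_components(f1$p, f2$p, n1, n2, h1, h2)
  data.frame(
    scaffold = gm$sites$scaffold, pos = gm$sites$pos,
    p1 = f1$p, p2 = f2$p, n1 = n1, n2 = n2,
    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
    stringsAsFactors = FALSE
  )
}

# Weir & Cockerham (1984) components for r = 2 populations, vectorized
# over sites. p: alt frequencies; n: individuals; h: observed het
# proportions.
wc_components <- function(p1, p2, n1, n2, h1, h2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2 & !is.na(h1) & !is.na(h2)
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / nsum
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  denom <- a + b + c
  theta <- ifelse(ok & denom != 0, a / denom, NA_real_)
  list(
    a = ifelse(ok, a, NA_real_), b = ifelse(ok, b, NA_real_),
    c = ifelse(ok, c, NA_real_), theta = theta
  )
}

#' Per-scaffold Z-normalization of window FST
#'
#' `FST' = (FST - scaffold mean) / scaffold sample SD` computed over the
#' non-missing windows of each scaffold. Scaffolds with fewer than two
#' non-missing windows, or zero SD, yield `NA` for all their windows (with
#' a warning naming them).
#'
#' @param values numeric vector of window FST values (`NA` = missing).
#' @param scaffold scaffold label per window.
#' @return Numeric vector of Z-scores, same length as `values`.
#' @export
z_normalize_per_scaffold <- function(values, scaffold) {
  out <- rep(NA_real_, length(values))
  degenerate <- character()
  for (s in unique(scaffold)) {
    idx <- which(scaffold == s)
    v <- values[idx]
    ok <- !is.na(v)
    if (sum(ok) < 2) { degenerate <- c(degenerate, s); next }
    sdv <- stats::sd(v[ok])
    if (sdv == 0) { degenerate <- c(degenerate, s); next }
    out[idx] <- (v - mean(v[ok])) / sdv
  }
  if (length(degenerate)) {
    warning("scaffold(s) with undefined Z-scores: ",
            paste(degenerate, collapse = ", "))
  }
  out
}

#' Net differentiation delta-FST'
#'
#' Subtracts the within-phenotype control comparison's Z-normalized window
#' FST from the between-phenotype comparison's, per orthologous window:
#' `delta = focal FST' - control FST'`. The two window tables must lie on
#' the same (scaffold, start) grid; missing on either side propagates.
#'
#' @param focal,control window tables as returned by [window_stats()] with
#'   an `fst_prime` column (see [z_normalize_per_scaffold()]).
#' @return The focal table with a `delta_fst_prime` column added, plus the
#'   control FST' as `fst_prime_control`.
#' @export
delta_fst_prime <- function(focal, control) {
  if (nrow(focal) != nrow(control) ||
      !identical(focal$scaffold, control$scaffold) ||
      !identical(focal$start, control$start)) {
    stop("focal and control window grids do not match")
  }
  out <- focal
  out$fst_prime_control <- control$fst_prime
  out$delta_fst_prime <- focal$fst_prime - control$fst_prime
  out
}

#' Full window table for a two-group comparison
#'
#' Convenience wrapper: [window_stats()] followed by per-scaffold
#' Z-normalization of the window FST into `fst_prime`.
#'
#' @inheritParams window_stats
#' @return The [window_stats()] table with an `fst_prime` column.
#' @export
comparison_windows <- function(gm, group1, group2, window_size = 2500,
                               min_snvs = 10) {
  w <- window_stats(gm, group1, group2, window_size, min_snvs)
  w$fst_prime <- z_normalize_per_scaffold(w$fst, w$scaffold)
  w
}

#' Genome-wide Hudson FST over sites (ratio of averages)
#'
#' `1 - mean((pi1 + pi2) / 2) / mean(dxy)` over all sites with defined
#' values in both groups; the single-number analogue of the windowed
#' estimator, used for parameter-recovery checks and fold-enrichment
#' denominators.
#'
#' @inheritParams window_stats
#' @return A single numeric FST value.
#' @export
global_fst_hudson <- function(gm, group1, group2) {
  f1 <- group_freq(gm, group1)
  f2 <- group_freq(gm, group2)
  pi1 <- site_pi(f1$p, f1$n)
  pi2 <- site_pi(f2$p, f2$n)
  dxy <- site_dxy(f1$p, f2$p)
  ok <- !is.na(pi1) & !is.na(pi2) & !is.na(dxy)
  if (!any(ok) || mean(dxy[ok]) == 0) return(NA_real_)
  1 - mean((pi1[ok] + pi2[ok]) / 2) / mean(dxy[ok])
}
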