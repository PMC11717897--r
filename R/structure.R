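#' Genotype principal component analysis
#'
#' Standard genotype PCA: each polymorphic site's dosage is standardized
#' as `(g - 2 p) / sqrt(2 p (1 - p))` with `p` the sample alt-allele
#' frequency; missing dosages are imputed to the site mean (0 after
#' centering); the sample x sample covariance of the standardized matrix
#' (scaled by the site count) is eigendecomposed.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample ids to restrict to.
#' @param n_components number of components to return (default 10, capped
#'   at the sample count).
#' @return list of class `pca_result`: `scores` (samples x components,
#'   eigenvector coordinates), `eigenvalues`, `varexp`
#'   (variance-explained fractions), `n_sites`, `samples`.
#' @export
pca_genotypes <- function(gm, samples = NULL, n_components = 10) {
  if (!is.null(samples)) gm <- gm_subset(gm, samples = samples)
  g <- gm$geno
  if (nrow(g) < 2) stop("PCA needs at least 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic; PCA undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  cov <- tcrossprod(x) / ncol(x)
  e <- eigen(cov, symmetric = TRUE)
  k <- min(n_components, nrow(g))
  ev <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$samples$sample
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = scores, eigenvalues = ev[seq_len(k)],
      varexp = ev[seq_len(k)] / sum(ev), n_sites = ncol(x),
      samples = gm$samples
    ),
    class = "pca_result"
  )
}

#' Method-of-Moments kinship for all sample pairs
#'
#' PLINK-style moment estimator: for each pair, observed counts of sites
#' with identity-by-state 0, 1 and 2 are matched against their
#' expectations given the cohort allele frequencies to give the IBD
#' probabilities `k0`, `k1`, `k2` (truncated to the feasible region and
#' renormalized); the kinship coefficient is `phi = k2/2 + k1/4`. The
#' conditional IBS-class expectations use unbiased (falling-factorial)
#' estimators of the allele-frequency monomials from the observed allele
#' counts, which removes the finite-sample inflation of the plug-in
#' estimator. Sites below the `maf_min` floor are excluded: near-fixed
#' variants carry almost no IBD information and destabilize the moments.
#' Pairs with fewer than `min_sites` informative sites are flagged
#' low-confidence with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param pairs optional 2-column matrix/data.frame of sample ids; default
#'   all pairs.
#' @param maf_min minimum minor-allele frequency for a site to be used
#'   (default 0.05).
#' @param min_sites informative-site count below which the estimate is
#'   flagged (default 1000).
#' @return data.frame: `sample1`, `sample2`, `k0`, `k1`, `k2`, `phi`,
#'   `n_sites`, `low_confidence`.
#' @export
kinship_mom <- function(gm, pairs = NULL, maf_min = 0.05, min_sites = 1000) {
  g <- gm$geno
  n_ok <- colSums(!is.na(g))
  X <- 2 * n_ok                      # total observed allele copies
  x <- colSums(g, na.rm = TRUE)      # alt copies
  p <- ifelse(X > 0, x / X, NA_real_)
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf_min & X >= 4
  g <- g[, keep, drop = FALSE]
  X <- X[keep]; x <- x[keep]
  y <- X - x                         # ref copies
  # unbiased estimator of p^a q^b from allele counts: falling factorials
  ff <- function(v, k) {
    out <- rep(1, length(v))
    for (i in seq_len(k)) out <- out * (v - i + 1)
    out
  }
  mono <- function(a, b) ff(x, a) * ff(y, b) / ff(X, a + b)
  # per-site IBS-class probabilities conditional on IBD state
  e0_z0 <- 2 * mono(2, 2)
  e1_z0 <- 4 * mono(3, 1) + 4 * mono(1, 3)
  e2_z0 <- mono(4, 0) + mono(0, 4) + 4 * mono(2, 2)
  e1_z1 <- 2 * mono(2, 1) + 2 * mono(1, 2)
  e2_z1 <- mono(3, 0) + mono(0, 3) + mono(2, 1) + mono(1, 2)
  ids <- gm$samples$sample
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2)
    pairs <- data.frame(sample1 = cmb[1, ], sample2 = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(sample1 = as.character(pairs[[1]]),
                        sample2 = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- g[match(pairs$sample1[i], ids), ]
    g2 <- g[match(pairs$sample2[i], ids), ]
    ok <- !is.na(g1) & !is.na(g2)
    ibs <- 2L - abs(g1[ok] - g2[ok])
    N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
    k0 <- N0 / sum(e0_z0[ok])
    k1 <- (N1 - k0 * sum(e1_z0[ok])) / sum(e1_z1[ok])
    k2 <- (N2 - k0 * sum(e2_z0[ok]) - k1 * sum(e2_z1[ok])) / sum(ok)
    k <- pmin(pmax(c(k0, k1, k2), 0), 1)
    k <- k / sum(k)
    c(k, k[3] / 2 + k[2] / 4, sum(ok))
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    pairs, k0 = res[, 1], k1 = res[, 2], k2 = res[, 3],
    phi = res[, 4], n_sites = as.integer(res[, 5]),
    low_confidence = res[, 5] < min_sites,
    stringsAsFactors = FALSE
  )
  if (any(out$low_confidence)) {
    warning(sum(out$low_confidence),
            " pair(s) estimated from fewer than ", min_sites,
            " informative sites")
  }
  out
}

#' Exclude related individuals (lower-depth member per pair)
#'
#' For every pair with kinship above the threshold, the member with the
#' lower genome-wide mean read depth is removed. Pairs are processed in
#' descending kinship; pairs whose members were already removed resolve
#' without further action. Depth ties remove the lexicographically
#' smaller id (logged via message).
#'
#' @param kinship table from [kinship_mom()].
#' @param samples sample sheet with `sample` and `mean_depth`.
#' @param threshold kinship threshold (default 0.1, strictly above).
#' @return Character vector of removed sample ids.
#' @export
apply_relatedness_exclusion <- function(kinship, samples, threshold = 0.1) {
  depth <- stats::setNames(samples$mean_depth, samples$sample)
  hits <- kinship[kinship$phi > threshold, , drop = FALSE]
  hits <- hits[order(-hits$phi), , drop = FALSE]
  removed <- character()
  for (i in seq_len(nrow(hits))) {
    a <- hits$sample1[i]; b <- hits$sample2[i]
    if (a %in% removed || b %in% removed) next
    if (depth[[a]] < depth[[b]]) {
      removed <- c(removed, a)
    } else if (depth[[b]] < depth[[a]]) {
      removed <- c(removed, b)
    } else {
      drop <- min(a, b)
      message("depth tie for pair (", a, ", ", b, "); removing ", drop)
      removed <- c(removed, drop)
    }
  }
  removed
}

#' Greedy LD pruning of a genotype matrix
#'
#' Sliding-window pruning of correlated sites (the standard preparation
#' for moment-based relatedness estimation, where pseudo-replicated sites
#' in strong LD would otherwise dominate the IBS counts): within each
#' window of `window` consecutive sites (advanced by `step`), sites whose
#' squared dosage correlation with an already-retained site exceeds
#' `r2_max` are dropped. Missing dosages are mean-imputed for the
#' correlation only.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in sites (default 50).
#' @param step window step in sites (default 5).
#' @param r2_max maximum tolerated r-squared (default 0.2).
#' @return The pruned [genotype_matrix()].
#' @export
ld_prune <- function(gm, window = 50, step = 5, r2_max = 0.2) {
  m <- ncol(gm$geno)
  x <- gm$geno
  p <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(m)) x[is.na(x[, j]), j] <- p[j]
  keep <- rep(TRUE, m)
  poly <- apply(x, 2, stats::sd) > 0
  keep[!poly] <- FALSE
  for (s in unique(gm$sites$scaffold)) {
    idx <- which(gm$sites$scaffold == s)
    starts <- seq(1, length(idx), by = step)
    for (st in starts) {
      win <- idx[st:min(st + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(stats::cor(x[, win, drop = FALSE])^2)
      for (a in 2:length(win)) {
        b <- seq_len(a - 1)
        b <- b[keep[win[b]]]
        if (length(b) && any(r2[b, a] > r2_max, na.rm = TRUE)) {
          keep[win[a]] <- FALSE
        }
      }
    }
  }
  gm_subset(gm, sites = keep)
}

#' Pairwise composite LD (r-squared of dosages)
#'
#' Squared Pearson correlation between unphased dosage vectors over
#' pairwise-complete samples (composite LD; phase-free). Pairs with fewer
#' than 4 complete observations are set to `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param scaffold restrict to one scaffold (`NULL` = all sites).
#' @param stride keep every `stride`-th polymorphic site (thinning).
#' @param max_sites random-free cap: if more sites remain than this, an
#'   evenly spaced subset is used.
#' @return list of class `ld_matrix`: `pos` (site positions), `scaffold`,
#'   `r2` (symmetric matrix with unit diagonal).
#' @export
ld_r2 <- function(gm, scaffold = NULL, stride = 1, max_sites = 400) {
  keep <- rep(TRUE, ncol(gm$geno))
  if (!is.null(scaffold)) keep <- gm$sites$scaffold == scaffold
  g <- gm$geno[, keep, drop = FALSE]
  pos <- gm$sites$pos[keep]
  scf <- gm$sites$scaffold[keep]
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]; pos <- pos[poly]; scf <- scf[poly]
  if (ncol(g) < 2) stop("need at least 2 polymorphic sites")
  idx <- seq(1, ncol(g), by = stride)
  if (length(idx) > max_sites) {
    idx <- idx[round(seq(1, length(idx), length.out = max_sites))]
  }
  g <- g[, idx, drop = FALSE]; pos <- pos[idx]; scf <- scf[idx]
  suppressWarnings(
    r <- stats::cor(g, use = "pairwise.complete.obs")
  )
  n_complete <- crossprod(!is.na(g))
  r2 <- r^2
  r2[n_complete < 4] <- NA_real_
  diag(r2) <- 1
  dimnames(r2) <- list(pos, pos)
  structure(list(pos = pos, scaffold = scf, r2 = r2), class = "ld_matrix")
}

# Exact 1-D 3-means: clusters of sorted values are contiguous, so the
# optimal partition is found by enumerating both split points with prefix
# sums. Deterministic; returns cluster labels ordered by center.
kmeans1d_exact <- function(x, k = 3) {
  stopifnot(k == 3)
  n <- length(x)
  o <- order(x)
  v <- x[o]
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  seg_ss <- function(i, j) {      # within-SS of v[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  best <- Inf
  bi <- 1L; bj <- 2L
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      ss <- seg_ss(1, i) + seg_ss(i + 1, j) + seg_ss(j + 1, n)
      if (ss < best) {
        best <- ss; bi <- i; bj <- j
      }
    }
  }
  lab <- integer(n)
  lab[o[1:bi]] <- 1L
  lab[o[(bi + 1):bj]] <- 2L
  lab[o[(bj + 1):n]] <- 3L
  lab
}

# Mean off-diagonal r2 of an ld_matrix.
mean_offdiag_r2 <- function(ld) {
  m <- ld$r2
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Detect the PCA/LD signature of a segregating inversion on a scaffold
#'
#' Runs a scaffold-restricted genotype PCA, partitions PC1 into three
#' clusters by exact one-dimensional 3-means (contiguous optimal
#' partition of the sorted scores; deterministic), and calls an inversion
#' when
#' (i) the PC1 clusters are separated — the smallest edge gap between
#' adjacent clusters exceeds `gap_threshold` times the PC1 standard
#' deviation; (ii) the middle cluster's mean per-individual
#' heterozygosity strictly exceeds both outer clusters' (inversion
#' heterozygotes are heterozygous across the block); and (iii) mean
#' composite r-squared among the scaffold's sites exceeds `ld_fold` times
#' the genome-wide background and does not extend into the comparison
#' scaffold.
#'
#' @param gm a [genotype_matrix()].
#' @param scaffold scaffold to test.
#' @param compare_scaffold adjacent scaffold used for the LD-confinement
#'   check (default: the first other scaffold).
#' @param gap_threshold cluster-separation constant (default 0.3).
#' @param ld_fold LD enrichment constant (default 3).
#' @param min_sites minimum polymorphic sites on the scaffold (default 50).
#' @return list of class `inversion_call`: `scaffold`, `detected`,
#'   `reason`, `clusters` (PC1 cluster per sample), `cluster_sizes`,
#'   `separation`, `cluster_het` (mean heterozygosity, ordered by PC1
#'   center), `ld_scaffold`, `ld_background`, `ld_compare`,
#'   `ld_confined`.
#' @export
detect_inversion_signature <- function(gm, scaffold, compare_scaffold = NULL,
                                       gap_threshold = 0.3, ld_fold = 3,
                                       min_sites = 50) {
  fail <- function(reason) {
    structure(list(
      scaffold = scaffold, detected = FALSE, reason = reason,
      clusters = NULL, cluster_sizes = NULL, separation = NA_real_,
      cluster_het = NULL, ld_scaffold = NA_real_, ld_background = NA_real_,
      ld_compare = NA_real_, ld_confined = NA
    ), class = "inversion_call")
  }
  on_scf <- gm$sites$scaffold == scaffold
  sub <- gm_subset(gm, sites = on_scf)
  p <- colMeans(sub$geno, na.rm = TRUE) / 2
  n_poly <- sum(!is.na(p) & p > 0 & p < 1)
  if (n_poly < min_sites) return(fail(sprintf("only %d polymorphic sites", n_poly)))

  pc1 <- pca_genotypes(sub, n_components = 2)$scores[, 1]
  if (length(unique(pc1)) < 3) return(fail("fewer than 3 distinct PC1 values"))

  cl <- kmeans1d_exact(pc1, k = 3)  # 1 = lowest-PC1 cluster, 3 = highest
  if (any(tabulate(cl, 3) == 0)) return(fail("empty PC1 cluster"))

  # edge gap between adjacent clusters, relative to the PC1 spread
  edge_gap <- function(lo, hi) min(pc1[cl == hi]) - max(pc1[cl == lo])
  separation <- min(edge_gap(1, 2), edge_gap(2, 3)) / stats::sd(pc1)

  het <- rowMeans(sub$geno == 1L, na.rm = TRUE)
  cluster_het <- vapply(1:3, function(k) mean(het[cl == k]), 0)

  bg_scf <- setdiff(unique(gm$sites$scaffold), scaffold)
  if (is.null(compare_scaffold)) compare_scaffold <- bg_scf[1]
  ld_scaffold <- mean_offdiag_r2(ld_r2(gm, scaffold))
  bg_only <- setdiff(bg_scf, compare_scaffold)
  if (!length(bg_only)) bg_only <- bg_scf
  # median across scaffolds so a single high-LD scaffold (e.g. another
  # inversion) cannot inflate the background
  ld_background <- stats::median(vapply(
    bg_only, function(s) mean_offdiag_r2(ld_r2(gm, s, max_sites = 150)), 0
  ))
  ld_compare <- if (!is.na(compare_scaffold)) {
    mean_offdiag_r2(ld_r2(gm, compare_scaffold))
  } else NA_real_
  ld_confined <- ld_scaffold > ld_fold * ld_background &&
    (is.na(ld_compare) || ld_compare < ld_fold * ld_background)

  sep_ok <- is.finite(separation) && separation > gap_threshold
  het_ok <- !anyNA(cluster_het) &&
    cluster_het[2] > cluster_het[1] && cluster_het[2] > cluster_het[3]
  detected <- sep_ok && het_ok && isTRUE(ld_confined)
  reason <- if (detected) "signature present" else paste(
    c(if (!sep_ok) "PC1 clusters not separated",
      if (!het_ok) "middle cluster heterozygosity not maximal",
      if (!isTRUE(ld_confined)) "LD not elevated/confined"),
    collapse = "; "
  )
  structure(list(
    scaffold = scaffold, detected = detected, reason = reason,
    clusters = stats::setNames(cl, sub$samples$sample),
    cluster_sizes = as.integer(table(factor(cl, 1:3))),
    separation = separation, cluster_het = cluster_het,
    ld_scaffold = ld_scaffold, ld_background = ld_background,
    ld_compare = ld_compare, ld_confined = ld_confined
  ), class = "inversion_call")
}

#' @exportS3Method base::print
print.inversion_call <- function(x, ...) {
  cat(sprintf(
    "<inversion_call> %s: %s (%s)\n", x$scaffold,
    if (x$detected) "DETECTED" else "not detected", x$reason
  ))
  if (!is.null(x$cluster_sizes)) {
    cat(sprintf(
      "  PC1 clusters %s, separation %.2f; het %s; LD %.3f vs background %.3f\n",
      paste(x$cluster_sizes, collapse = "/"), x$separation,
      paste(sprintf("%.3f", x$cluster_het), collapse = "/"),
      x$ld_scaffold, x$ld_background
    ))
  }
  invisible(x)
}
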