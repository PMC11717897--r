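# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: scalar loops, literal formula transcriptions, and
# exhaustive scans, used to pin down the estimators to 1e-12.

# Allele frequency and copy count from one group's genotype vector.
oracle_freq <- function(g) {
  n <- 0L
  alt <- 0L
  for (x in g) {
    if (!is.na(x)) {
      n <- n + 2L
      alt <- alt + x
    }
  }
  list(p = if (n > 0) alt / n else NA_real_, n = n)
}

oracle_site_pi <- function(g) {
  f <- oracle_freq(g)
  if (is.na(f$p) || f$n < 2) return(NA_real_)
  2 * f$p * (1 - f$p) * f$n / (f$n - 1)
}

oracle_site_dxy <- function(g1, g2) {
  f1 <- oracle_freq(g1)
  f2 <- oracle_freq(g2)
  if (is.na(f1$p) || is.na(f2$p)) return(NA_real_)
  f1$p * (1 - f2$p) + f2$p * (1 - f1$p)
}

# Hudson window FST: straight-line site-by-site evaluation, ratio of
# averages over usable sites. G1/G2: individuals x sites matrices.
oracle_hudson_window <- function(G1, G2) {
  pi1s <- pi2s <- dxys <- c()
  for (j in seq_len(ncol(G1))) {
    p1 <- oracle_site_pi(G1[, j])
    p2 <- oracle_site_pi(G2[, j])
    d <- oracle_site_dxy(G1[, j], G2[, j])
    if (!is.na(p1) && !is.na(p2) && !is.na(d)) {
      pi1s <- c(pi1s, p1); pi2s <- c(pi2s, p2); dxys <- c(dxys, d)
    }
  }
  if (!length(dxys) || mean(dxys) == 0) {
    return(list(pi1 = NA, pi2 = NA, dxy = NA, fst = NA, n = length(dxys)))
  }
  list(
    pi1 = mean(pi1s), pi2 = mean(pi2s), dxy = mean(dxys),
    fst = 1 - ((mean(pi1s) + mean(pi2s)) / 2) / mean(dxys), n = length(dxys)
  )
}

# Weir & Cockerham (1984) theta-hat for one site and two groups: literal
# transcription of the r = 2 equations.
oracle_wc_theta <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- sum(g1 == 1) / n1; h2 <- sum(g2 == 1) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Tajima's D: constants recomputed by direct summation.
oracle_tajima_d <- function(S, pi_sum, n) {
  if (S <= 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Cluster caller oracle: explicit index scan. flags over
# {"outlier", "background", NA}; missing windows are skipped (never break
# or extend runs); background breaks runs; runs of >= min_windows outlier
# windows become clusters.
oracle_clusters <- function(flags, min_windows = 5) {
  out <- rep(NA_integer_, length(flags))
  nid <- 0L
  run <- integer()  # indices of the current outlier run
  flush <- function() {
    if (length(run) >= min_windows) {
      nid <<- nid + 1L
      out[run] <<- nid
    }
    run <<- integer()
  }
  for (i in seq_along(flags)) {
    f <- flags[i]
    if (is.na(f)) next
    if (f == "outlier") run <- c(run, i) else flush()
  }
  flush()
  out
}

# Mean silhouette width over euclidean distances, for checking PCA
# cluster separation without extra dependencies.
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
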