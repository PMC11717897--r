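test_that("per-site pi and Dxy match their closed forms", {
  expect_equal(site_pi(0.5, 4), 2 / 3)      # 2 alt of 4 copies
  expect_equal(site_pi(0, 10), 0)           # monomorphic
  expect_equal(site_pi(0.5, 2), 1)          # n = 2, one alt
  expect_true(is.na(site_pi(0.5, 1)))       # too few copies
  expect_equal(site_dxy(0.5, 0.5), 0.5)
  expect_equal(site_dxy(0, 1), 1)
  expect_equal(site_dxy(0, 0), 0)
  expect_true(is.na(site_dxy(NA, 0.5)))
})

test_that("windowed Hudson FST handles the degenerate endpoint cases", {
  # identical genotype columns in both groups: pi carries the unbiased
  # n/(n-1) factor while Dxy does not, so FST is exactly -1/(n-1); the
  # estimator is centered on zero only across independent samples
  g <- random_geno(8, 15, missing_rate = 0)
  gm <- gm_from_geno(rbind(g, g), pos = 1:15 * 100L)
  ids <- gm$samples$sample
  w <- window_stats(gm, ids[1:8], ids[9:16], min_snvs = 1)
  expect_equal(w$fst, -1 / 15, tolerance = 1e-12)
  # two independent draws from one population: FST near zero
  withr::with_seed(61, {
    p <- runif(4000, 0.05, 0.95)
    ga <- matrix(rbinom(20 * 4000, 2, rep(p, each = 20)), 20, 4000)
    gb <- matrix(rbinom(20 * 4000, 2, rep(p, each = 20)), 20, 4000)
  })
  gm0 <- gm_from_geno(rbind(ga, gb), pos = sort(sample(1:2e6, 4000)))
  f0 <- global_fst_hudson(gm0, gm0$samples$sample[1:20], gm0$samples$sample[21:40])
  expect_lt(abs(f0), 0.01)
  # fixed differences: pi = 0, dxy = 1, FST = 1
  gfix <- rbind(matrix(0L, 6, 12), matrix(2L, 6, 12))
  gmf <- gm_from_geno(gfix, pos = 1:12 * 50L)
  wf <- window_stats(gmf, gmf$samples$sample[1:6], gmf$samples$sample[7:12])
  expect_equal(wf$pi1, 0)
  expect_equal(wf$dxy, 1)
  expect_equal(wf$fst, 1)
  # empty group rejected
  expect_error(window_stats(gm, character(), ids[1:4]), "non-empty")
})

test_that("windowed statistics agree with a site-by-site oracle", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      m <- sample(12:30, 1)
      g1 <- random_geno(n1, m, missing_rate = 0.15)
      g2 <- random_geno(n2, m, missing_rate = 0.15)
      gm <- gm_from_geno(rbind(g1, g2), pos = sort(sample(1:2400, m)))
      ids <- gm$samples$sample
      w <- window_stats(gm, ids[1:n1], ids[n1 + 1:n2], min_snvs = 1)
      o <- oracle_hudson_window(g1, g2)
      expect_equal(w$n_snvs, o$n)
      if (!is.na(o$fst)) {
        expect_equal(w$fst, o$fst, tolerance = 1e-12)
        expect_equal(w$pi1, o$pi1, tolerance = 1e-12)
        expect_equal(w$dxy, o$dxy, tolerance = 1e-12)
      }
    }
  })
})

test_that("Weir-Cockerham theta matches a literal 1984 transcription", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      g1 <- random_geno(5, 10, missing_rate = 0.2)
      g2 <- random_geno(7, 10, missing_rate = 0.2)
      gm <- gm_from_geno(rbind(g1, g2))
      ids <- gm$samples$sample
      wc <- per_snv_fst_wc(gm, ids[1:5], ids[6:12])
      for (j in 1:10) {
        o <- oracle_wc_theta(g1[, j], g2[, j])
        if (is.na(o)) expect_true(is.na(wc$theta[j]))
        else expect_equal(wc$theta[j], o, tolerance = 1e-12)
      }
    }
  })
  # no among-population variance: theta <= 0
  g <- random_geno(6, 20, missing_rate = 0)
  gm <- gm_from_geno(rbind(g, g))
  wc <- per_snv_fst_wc(gm, gm$samples$sample[1:6], gm$samples$sample[7:12])
  expect_true(all(wc$theta[!is.na(wc$theta)] <= 1e-12))
  # monomorphic site: missing
  gm0 <- gm_from_geno(matrix(0L, 8, 1))
  wc0 <- per_snv_fst_wc(gm0, gm0$samples$sample[1:4], gm0$samples$sample[5:8])
  expect_true(is.na(wc0$theta))
})

test_that("Tajima's D follows the Watterson-constant formula", {
  # the frozen value below comes from the direct-summation oracle
  expect_equal(oracle_tajima_d(16, 3.888, 10), -1.4468996210899, tolerance = 1e-10)
  expect_equal(tajima_d(16, 3.888, 10), oracle_tajima_d(16, 3.888, 10),
               tolerance = 1e-12)
  # numerator vanishes when pi_sum = S / a1
  a1 <- sum(1 / (1:9))
  expect_equal(tajima_d(5, 5 / a1, 10), 0)
  # singleton-only windows are negative for n > 2
  n <- 20
  S <- 8
  pi_singleton <- S * 2 * (1 / n) * ((n - 1) / n) * (n / (n - 1))
  expect_lt(tajima_d(S, pi_singleton, n), 0)
  expect_true(is.na(tajima_d(0, 0, 10)))
  expect_error(tajima_d(3, 1, 3), "at least 4")
})

test_that("per-scaffold Z-normalization centers and scales each scaffold", {
  expect_equal(z_normalize_per_scaffold(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  expect_warning(
    out <- z_normalize_per_scaffold(c(2, 2, 2), rep("a", 3)),
    "undefined"
  )
  expect_true(all(is.na(out)))
  withr::with_seed(5, {
    v <- rnorm(40)
    s <- rep(c("a", "b"), each = 20)
    z <- z_normalize_per_scaffold(v, s)
    for (sc in c("a", "b")) {
      expect_equal(mean(z[s == sc]), 0, tolerance = 1e-12)
      expect_equal(sd(z[s == sc]), 1, tolerance = 1e-12)
    }
  })
})

test_that("delta-FST' subtracts control from focal and is antisymmetric", {
  w <- data.frame(scaffold = "s1", start = c(1, 2501), fst_prime = c(2, 0.5))
  ctl <- data.frame(scaffold = "s1", start = c(1, 2501), fst_prime = c(0.5, 0.5))
  d <- delta_fst_prime(w, ctl)
  expect_equal(d$delta_fst_prime, c(1.5, 0))
  # antisymmetry under swapping focal and control
  d2 <- delta_fst_prime(ctl, w)
  expect_equal(d2$delta_fst_prime, -d$delta_fst_prime)
  # grid mismatch rejected
  bad <- ctl
  bad$start <- bad$start + 1
  expect_error(delta_fst_prime(w, bad), "grids do not match")
})

test_that("windows tile scaffolds from position 1 in fixed steps", {
  g <- random_geno(6, 50, missing_rate = 0)
  pos <- sort(sample(1:20000, 50))
  gm <- gm_from_geno(g, pos = pos)
  ids <- gm$samples$sample
  w <- window_stats(gm, ids[1:3], ids[4:6], min_snvs = 1)
  expect_true(all(w$start %% 2500 == 1))
  expect_true(all(w$end - w$start == 2499))
  # every site falls inside its window
  for (i in seq_len(nrow(w))) {
    inside <- pos >= w$start[i] & pos <= w$end[i]
    expect_gte(sum(inside), 1)
  }
})
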