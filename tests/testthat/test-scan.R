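fake_windows <- function(delta, scaffold = rep("s1", length(delta))) {
  data.frame(
    scaffold = scaffold,
    start = unlist(lapply(table(scaffold)[unique(scaffold)],
                          function(k) seq_len(k) * 2500 - 2499)),
    end = unlist(lapply(table(scaffold)[unique(scaffold)],
                        function(k) seq_len(k) * 2500)),
    delta_fst_prime = delta,
    stringsAsFactors = FALSE
  )
}

test_that("outlier calling uses the strict 99th-percentile rule", {
  w <- fake_windows(as.numeric(1:100))
  out <- call_outliers(w)
  expect_equal(attr(out, "threshold"), 99.01)
  expect_identical(which(out$flag == "outlier"), 100L)
  # constant input: nothing exceeds the threshold
  wc <- call_outliers(fake_windows(rep(1, 150)))
  expect_false(any(wc$flag == "outlier"))
  # roughly 1% of continuous random input flagged
  withr::with_seed(8, {
    wr <- call_outliers(fake_windows(rnorm(5000)))
  })
  expect_equal(sum(wr$flag == "outlier") / 5000, 0.01, tolerance = 0.005)
  # missing flags propagate, all-missing input errors
  wm <- fake_windows(c(NA, 1:199))
  expect_true(is.na(call_outliers(wm)$flag[1]))
  expect_error(call_outliers(fake_windows(rep(NA_real_, 10))), "all windows missing")
})

test_that("cluster calling skips missing windows and breaks on background", {
  O <- "outlier"; N <- "background"
  expect_equal(call_clusters(c(O, O, O, O, O)), rep(1L, 5))
  # missing windows do not break or lengthen a run
  got <- call_clusters(c(O, O, NA, O, O, O))
  expect_equal(got, c(1L, 1L, NA, 1L, 1L, 1L))
  # a background window breaks the run
  expect_true(all(is.na(call_clusters(c(O, O, O, O, N, O)))))
  # clusters never span scaffolds
  flags <- rep(O, 10)
  scf <- rep(c("a", "b"), each = 5)
  expect_equal(call_clusters(flags, scf), rep(c(1L, 2L), each = 5))
})

test_that("cluster calling equals the exhaustive oracle on random strings", {
  lv <- c("outlier", "background", NA)
  withr::with_seed(30, {
    for (rep in 1:400) {
      flags <- sample(lv, sample(1:14, 1), replace = TRUE)
      expect_identical(call_clusters(flags, min_windows = 3),
                       oracle_clusters(flags, min_windows = 3))
      expect_identical(call_clusters(flags), oracle_clusters(flags))
    }
  })
})

test_that("cluster summaries compute the report-table columns", {
  w <- fake_windows(c(5, 6, 7, 8, 9, 0))
  w$fst <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0)
  w$tajima_d1 <- c(-1, -2, -3, -4, -5, 0)
  w$tajima_d2 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0)
  w$flag <- c(rep("outlier", 5), "background")
  cl <- call_clusters(w$flag)
  s <- summarize_clusters(w, cl)
  expect_equal(s$n_windows, 5L)
  expect_equal(s$mean_delta_fst_prime, 7)
  expect_equal(s$mean_fst, 0.3)
  expect_equal(s$median_fst, 0.3)
  expect_equal(s$mean_tajima_d1, -3)
  expect_equal(s$mean_tajima_d2, 0.3)
  # even member count: midpoint median
  cl4 <- c(1L, 1L, 1L, 1L, NA, NA)
  s4 <- summarize_clusters(w, cl4)
  expect_equal(s4$median_fst, 0.25)
  # single-window cluster: summary equals the window's own values
  s1 <- summarize_clusters(w, c(1L, rep(NA, 5)))
  expect_equal(s1$mean_fst, 0.1)
  expect_equal(s1$n_windows, 1L)
})

test_that("shared outlier windows equal the set intersection", {
  w1 <- fake_windows(rnorm(50))
  withr::with_seed(4, {
    w1$flag <- sample(c("outlier", "background", NA), 50, replace = TRUE)
    w2 <- w1
    w2$flag <- sample(c("outlier", "background", NA), 50, replace = TRUE)
  })
  got <- shared_outlier_windows(w1, w2)
  manual <- sum(
    !is.na(w1$flag) & !is.na(w2$flag) &
      w1$flag == "outlier" & w2$flag == "outlier"
  )
  expect_equal(got$n_shared, manual)
  # identical flag vectors: count equals the per-vector outlier count
  same <- shared_outlier_windows(w1, w1)
  expect_equal(same$n_shared, sum(w1$flag == "outlier", na.rm = TRUE))
  # disjoint outlier sets
  w3 <- w1
  w3$flag <- ifelse(!is.na(w1$flag) & w1$flag == "outlier", "background", "outlier")
  expect_equal(shared_outlier_windows(w1, w3)$n_shared, 0)
  # grid mismatch rejected
  w4 <- w2[-1, ]
  expect_error(shared_outlier_windows(w1, w4), "grids")
})

test_that("the cluster Tajima's D contrast behaves under null and shift", {
  withr::with_seed(12, {
    genome <- rnorm(800, -0.5, 0.8)
    # null: cluster drawn from the genome-wide set itself
    p_null <- replicate(100, {
      compare_cluster_tajimas_d(sample(genome, 8), genome)$p_value
    })
    expect_gt(mean(p_null), 0.3)
    expect_lt(mean(p_null), 0.7)
    # shifted cluster: small p
    p_shift <- compare_cluster_tajimas_d(sample(genome, 10) - 1.5, genome)$p_value
    expect_lt(p_shift, 0.01)
  })
  # degenerate all-tied input
  expect_warning(res <- compare_cluster_tajimas_d(c(1, 1), c(1, 1, 1)), "tied")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
})

test_that("genotype-class counts follow the documented conventions", {
  g <- matrix(c(1L, 1L, 2L), 3, 1)
  gm <- gm_from_geno(g, pos = 500L)
  got <- genotype_class_counts(gm, "s1", 1, 1000, gm$samples$sample)
  expect_equal(got$het_genotypes, 2L)
  expect_equal(got$hom_alt_genotypes, 1L)
  expect_equal(got$het_sites, 1L)      # modal class is heterozygous
  expect_equal(got$hom_alt_sites, 0L)
  # all-reference region
  gm0 <- gm_from_geno(matrix(0L, 3, 4))
  z <- genotype_class_counts(gm0, "s1", 1, 100, gm0$samples$sample)
  expect_equal(z$het_genotypes + z$hom_alt_genotypes, 0L)
  # empty region
  e <- genotype_class_counts(gm0, "s1", 5000, 6000, gm0$samples$sample)
  expect_equal(e$n_sites, 0L)
})

test_that("scaffold fold-enrichment is a ratio of mean window FST", {
  w <- data.frame(scaffold = rep(c("a", "b"), each = 5),
                  fst = c(rep(0.2, 5), rep(0.04, 5)))
  fe <- scaffold_fold_enrichment(w, "a", other = "b")
  expect_equal(fe$fold_genome, 0.2 / 0.12)
  expect_equal(fe$fold_other, 5)
  # scaffold equal to the genome mean
  w2 <- data.frame(scaffold = rep(c("a", "b"), each = 5), fst = rep(0.1, 10))
  expect_equal(scaffold_fold_enrichment(w2, "a")$fold_genome, 1)
})
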