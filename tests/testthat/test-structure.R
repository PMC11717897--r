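test_that("genotype PCA separates structured populations but not panmictic groups", {
  # three populations diverged at F = 0.1 separate cleanly on PC1/PC2
  cfg <- sim_config(
    seed = 31,
    scaffolds = data.frame(name = "s1", length = 1e6, chromosome = "chr1"),
    n_sites_per_scaffold = 4000L,
    populations = data.frame(name = c("pA", "pB", "pC"), n = c(10L, 10L, 10L),
                             F = c(0.1, 0.1, 0.1)),
    focal_population = "pA", phenotypes = c("x", "y"),
    selected_region = NULL, inversion = NULL,
    sfs_skew = 1, missing_rate = 0.02, repeat_fraction = 0
  )
  co <- simulate_cohort(cfg)
  pc <- pca_genotypes(co$gm)
  sil <- mean_silhouette(pc$scores[, 1:2], co$gm$samples$population)
  expect_gt(sil, 0.5)
  # eigen spectrum invariants
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_true(all(pc$eigenvalues >= -1e-8))
  expect_lte(sum(pc$varexp), 1 + 1e-8)

  # a panmictic population split into two labels shows no separation
  co2 <- simulate_cohort(flat_config(seed = 32, n = 24L, n_sites = 4000,
                                     missing_rate = 0.02))
  pc2 <- pca_genotypes(co2$gm)
  sil2 <- mean_silhouette(pc2$scores[, 1:4], co2$gm$samples$phenotype)
  expect_lt(sil2, 0.2)

  # duplicated samples land on identical coordinates
  g <- random_geno(6, 300, missing_rate = 0)
  gm <- gm_from_geno(rbind(g, g[1, , drop = FALSE]))
  pc3 <- pca_genotypes(gm)
  # compare only well-separated leading components; trailing near-zero
  # eigenvalues have arbitrary orientation
  expect_equal(unname(pc3$scores[1, 1:3]), unname(pc3$scores[7, 1:3]),
               tolerance = 1e-8)
  # all-monomorphic input rejected
  expect_error(pca_genotypes(gm_from_geno(matrix(0L, 4, 10))), "monomorphic")
})

test_that("Method-of-Moments kinship recovers pedigree relationships", {
  cfg <- flat_config(seed = 41, n = 20L, n_sites = 20000L, missing_rate = 0.02)
  co <- simulate_cohort(cfg)
  co <- append_related_pair(co, "p1_01")                 # parent-offspring
  co <- append_related_pair(co, "p1_02", mode = "clone") # duplicate
  ped <- co$truth$pedigree
  kin <- kinship_mom(co$gm, pairs = data.frame(
    s1 = c(ped$parent, "p1_05"),
    s2 = c(ped$offspring, "p1_06")
  ))
  expect_gt(kin$phi[1], 0.22); expect_lt(kin$phi[1], 0.28)
  expect_gt(kin$phi[2], 0.47); expect_lte(kin$phi[2], 0.5)
  expect_lt(kin$phi[3], 0.05)
  expect_true(all(abs(kin$k0 + kin$k1 + kin$k2 - 1) < 1e-12))
  # a sample against itself behaves like a duplicate
  self <- kinship_mom(co$gm, pairs = data.frame(s1 = "p1_03", s2 = "p1_03"))
  expect_gt(self$phi, 0.47)
  # few informative sites triggers the low-confidence warning
  small <- gm_from_geno(random_geno(6, 50, missing_rate = 0))
  expect_warning(kinship_mom(small), "informative sites")
})

test_that("the relatedness exclusion removes the lower-depth member", {
  samples <- data.frame(sample = c("a", "b", "c"), mean_depth = c(12, 9, 9))
  kin1 <- data.frame(sample1 = "a", sample2 = "b", phi = 0.26)
  expect_identical(apply_relatedness_exclusion(kin1, samples), "b")
  # nothing above threshold: nothing removed
  kin0 <- data.frame(sample1 = "a", sample2 = "b", phi = 0.05)
  expect_length(apply_relatedness_exclusion(kin0, samples), 0)
  # depth tie: lexicographically smaller id, logged
  kin_tie <- data.frame(sample1 = "c", sample2 = "b", phi = 0.3)
  expect_message(out <- apply_relatedness_exclusion(kin_tie, samples), "tie")
  expect_identical(out, "b")
  # triangle of mutually related samples: no surviving pair stays related
  tri_samples <- data.frame(sample = c("a", "b", "c"), mean_depth = c(10, 8, 6))
  tri <- data.frame(sample1 = c("a", "a", "b"), sample2 = c("b", "c", "c"),
                    phi = c(0.3, 0.28, 0.26))
  removed <- apply_relatedness_exclusion(tri, tri_samples)
  left <- tri[!(tri$sample1 %in% removed) & !(tri$sample2 %in% removed), ]
  expect_true(all(left$phi <= 0.1))
})

test_that("composite LD r2 is symmetric, bounded and relabeling-invariant", {
  withr::with_seed(51, {
    g <- random_geno(48, 40, missing_rate = 0.05)
  })
  g[, 2] <- g[, 1]          # identical pair
  g[, 3] <- 2L - g[, 1]     # complementary pair
  gm <- gm_from_geno(g)
  ld <- ld_r2(gm)
  expect_equal(ld$r2, t(ld$r2))
  expect_true(all(ld$r2 >= -1e-12 & ld$r2 <= 1 + 1e-12, na.rm = TRUE))
  i <- match(10L, ld$pos); j <- match(20L, ld$pos); k <- match(30L, ld$pos)
  expect_equal(ld$r2[i, j], 1, tolerance = 1e-12)
  expect_equal(ld$r2[i, k], 1, tolerance = 1e-12)
  # independent sites: near-zero mean off-diagonal r2
  withr::with_seed(52, {
    gi <- random_geno(48, 60, missing_rate = 0)
  })
  ldi <- ld_r2(gm_from_geno(gi))
  off <- ldi$r2[upper.tri(ldi$r2)]
  expect_lt(mean(off, na.rm = TRUE), 0.05)
  # pairs with < 4 complete observations are masked
  gs <- matrix(c(0L, 1L, 2L, 1L, 0L,
                 2L, 0L, 1L, 1L, 2L), 5, 2)
  gs[1:2, 1] <- NA
  gs[3:4, 2] <- NA          # only 1 complete observation for the pair
  lds <- ld_r2(gm_from_geno(gs))
  i <- match(10L, lds$pos); j <- match(20L, lds$pos)
  expect_true(is.na(lds$r2[i, j]))
})

test_that("the inversion signature detector finds planted inversions only", {
  co <- default_cohort()
  d <- withr::local_tempdir()
  p <- write_cohort(co, d)
  gm <- filter_chain(read_vcf(p$vcf, p$samples), bed = p$bed)$gm
  call <- detect_inversion_signature(gm, "scaffold_4")
  expect_true(call$detected)
  # karyotype clusters recover the simulated inversion genotypes
  ig <- co$truth$inversion_genotype[names(call$clusters)]
  expect_gt(adjusted_rand(call$clusters, ig), 0.9)
  # middle cluster = heterozygotes, maximal heterozygosity
  expect_gt(call$cluster_het[2], max(call$cluster_het[c(1, 3)]))
  # clusters do not mirror geography (inversion segregates in 2 populations)
  pops <- gm$samples$population[match(names(call$clusters), gm$samples$sample)]
  expect_lt(adjusted_rand(call$clusters, pops), 0.5)
  # scaffolds without an inversion are not called
  call0 <- detect_inversion_signature(gm, "scaffold_1")
  expect_false(call0$detected)
})
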