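# Shared fixture builders. Cohorts are generated in code at test time;
# the default-size cohort is cached per session because several test files
# exercise it.

toy_path <- function(f) {
  p <- system.file("extdata", f, package = "migrascan")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", f)
  p
}

# A small genotype_matrix built directly from a genotype matrix, with
# pass-everything site annotations.
gm_from_geno <- function(geno, pos = NULL, scaffold = "s1",
                         populations = NULL, phenotypes = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  if (is.null(populations)) populations <- rep("pop1", n)
  if (is.null(phenotypes)) phenotypes <- rep("none", n)
  genotype_matrix(
    geno,
    data.frame(scaffold = rep_len(scaffold, m), pos = pos,
               ref = "A", alt = "G", qual = 100, dp = 10L * n, mq = 60,
               rpbz = 0, stringsAsFactors = FALSE),
    data.frame(sample = sprintf("i%02d", seq_len(n)),
               population = populations, phenotype = phenotypes,
               mean_depth = 15, stringsAsFactors = FALSE)
  )
}

# Random small genotype matrices for oracle comparisons.
random_geno <- function(n_ind, n_sites, maf_range = c(0.05, 0.95),
                        missing_rate = 0.1) {
  p <- runif(n_sites, maf_range[1], maf_range[2])
  g <- matrix(rbinom(n_ind * n_sites, 2, rep(p, each = n_ind)), n_ind, n_sites)
  if (missing_rate > 0) {
    g[matrix(runif(n_ind * n_sites) < missing_rate, n_ind, n_sites)] <- NA
  }
  g
}

# One-scaffold single-population config used by several calibration tests.
flat_config <- function(seed, n = 12L, n_sites = 20000L, len = 1e6,
                        sfs_skew = 1, F = 0, missing_rate = 0) {
  sim_config(
    seed = seed,
    scaffolds = data.frame(name = "s1", length = len, chromosome = "chr1"),
    n_sites_per_scaffold = n_sites,
    populations = data.frame(name = "p1", n = n, F = F),
    focal_population = "p1", phenotypes = c("a", "b"),
    selected_region = NULL, inversion = NULL, sfs_skew = sfs_skew,
    missing_rate = missing_rate, repeat_fraction = 0
  )
}

# Default-condition cohort, simulated once per session.
.default_cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 42L) {
  key <- paste0("seed", seed)
  if (is.null(.default_cohort_cache[[key]])) {
    .default_cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  }
  .default_cohort_cache[[key]]
}
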