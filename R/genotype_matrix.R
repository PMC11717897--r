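#' Genotype matrix container
#'
#' Bundles a samples x sites matrix of alt-allele dosages (0/1/2, `NA` =
#' missing) with per-site metadata (scaffold, 1-based position, ref/alt
#' alleles, QUAL, INFO DP, MQ, RPBZ), per-sample read depths of the same
#' shape, and a sample sheet (id, population, phenotype, mean depth). Every
#' statistic in the package operates on this object.
#'
#' @param geno integer matrix, samples x sites, values in {0,1,2,NA}.
#' @param sites data.frame with columns `scaffold`, `pos`, `ref`, `alt`,
#'   `qual`, `dp`, `mq`, `rpbz` (one row per site, same order as columns of
#'   `geno`).
#' @param samples data.frame with columns `sample`, `population`,
#'   `phenotype`, `mean_depth` (one row per row of `geno`).
#' @param dp optional integer matrix of per-sample per-site read depths,
#'   same shape as `geno`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples, dp = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(
    nrow(sites) == ncol(geno),
    nrow(samples) == nrow(geno),
    all(c("scaffold", "pos") %in% names(sites)),
    all(c("sample", "population") %in% names(samples))
  )
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(all(dim(dp) == dim(geno)))
  }
  if (anyDuplicated(sites[, c("scaffold", "pos")])) {
    stop("duplicate (scaffold, position) entries in site table")
  }
  o <- order(sites$scaffold, sites$pos)
  if (is.unsorted(o)) {
    geno <- geno[, o, drop = FALSE]
    sites <- sites[o, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[, o, drop = FALSE]
  }
  rownames(geno) <- samples$sample
  rownames(sites) <- NULL
  structure(
    list(geno = geno, sites = sites, samples = samples, dp = dp),
    class = "genotype_matrix"
  )
}

.datatable.aware <- TRUE

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d biallelic SNVs on %d scaffold(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$sites$scaffold))
  ))
  cat("populations:", paste(sprintf(
    "%s=%d", names(table(x$samples$population)), table(x$samples$population)
  ), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids, or logical/integer index
#'   over rows; `NULL` keeps all.
#' @param sites logical/integer index over sites; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  ri <- seq_len(nrow(gm$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) {
      miss <- setdiff(samples, gm$samples$sample)
      if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
      match(samples, gm$samples$sample)
    } else which(rep_len(TRUE, nrow(gm$geno)))[samples]
  }
  ci <- seq_len(ncol(gm$geno))
  if (!is.null(sites)) ci <- ci[sites]
  genotype_matrix(
    gm$geno[ri, ci, drop = FALSE],
    gm$sites[ci, , drop = FALSE],
    gm$samples[ri, , drop = FALSE],
    dp = if (!is.null(gm$dp)) gm$dp[ri, ci, drop = FALSE]
  )
}

#' Sample ids belonging to a population or phenotype group
#'
#' @param gm a [genotype_matrix()].
#' @param population population label, or `NULL`.
#' @param phenotype phenotype label, or `NULL`; combined with `population`
#'   by AND.
#' @return Character vector of sample ids.
#' @export
gm_group <- function(gm, population = NULL, phenotype = NULL) {
  keep <- rep(TRUE, nrow(gm$samples))
  if (!is.null(population)) keep <- keep & gm$samples$population %in% population
  if (!is.null(phenotype)) keep <- keep & gm$samples$phenotype %in% phenotype
  gm$samples$sample[keep]
}

# Per-site alt-allele frequency and non-missing allele-copy count for a set
# of sample ids. Returns list(p, n) of length n_sites; p is NA where n == 0.
group_freq <- function(gm, ids) {
  g <- gm$geno[match(ids, gm$samples$sample), , drop = FALSE]
  n <- 2L * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p <- ifelse(n > 0L, alt / n, NA_real_)
  list(p = p, n = n, alt = alt)
}

# Observed heterozygote proportion per site among non-missing genotypes.
group_het <- function(gm, ids) {
  g <- gm$geno[match(ids, gm$samples$sample), , drop = FALSE]
  nn <- colSums(!is.na(g))
  ifelse(nn > 0L, colSums(g == 1L, na.rm = TRUE) / nn, NA_real_)
}
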