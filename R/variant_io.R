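#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (via vcfR), keeps biallelic SNV records only (multi-allelic
#' records and indels are dropped and counted), converts GT to alt-allele
#' dosage 0/1/2 (phase-insensitive; `./.` becomes `NA`), and attaches the
#' sample sheet. Site-level QUAL and INFO DP/MQ/RPBZ and per-sample FORMAT
#' DP are carried along.
#'
#' @param vcf_path path to an (optionally bgzipped) VCF v4.2.
#' @param sample_sheet data.frame with `sample`, `population`, `phenotype`,
#'   `mean_depth`, or a path to such a TSV.
#' @return A [genotype_matrix()]; the number of dropped non-biallelic/indel
#'   records is attached as attribute `"n_dropped_records"`.
#' @export
read_vcf <- function(vcf_path, sample_sheet) {
  if (is.character(sample_sheet)) {
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing_sheet <- setdiff(vcf_samples, sample_sheet$sample)
  if (length(missing_sheet)) {
    stop("VCF samples absent from sample sheet: ",
         paste(missing_sheet, collapse = ", "))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snv <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snv)
  v <- v[snv, ]
  fix <- fix[snv, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  )
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  sites <- data.frame(
    scaffold = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    dp = as.integer(info_num("DP")),
    mq = info_num("MQ"), rpbz = info_num("RPBZ"),
    stringsAsFactors = FALSE
  )
  sheet <- sample_sheet[match(vcf_samples, sample_sheet$sample), , drop = FALSE]
  gm <- genotype_matrix(
    t(dosage), sites, sheet,
    dp = if (!all(is.na(dp))) t(dp)
  )
  attr(gm, "n_dropped_records") <- n_dropped
  gm
}

#' Read a BED file of repeat intervals
#'
#' @param path BED path (0-based half-open intervals). Unsorted input is
#'   sorted internally with a warning.
#' @return data.frame with `scaffold`, `start` (0-based), `end`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("scaffold", "start", "end")
  if (is.unsorted(order(bed$scaffold, bed$start))) {
    warning("BED intervals unsorted; sorting internally")
  }
  bed[order(bed$scaffold, bed$start), ]
}

#' Site-level filter chain (QUAL / depth / MQ / RPBZ)
#'
#' Retains sites with `QUAL > min_qual`, INFO `DP` strictly greater than
#' the number of samples and strictly less than twice the mean INFO DP
#' (mean taken over the pre-filter site set), `MQ > min_mq`, and RPBZ
#' inside `rpbz_range` (bounds inclusive).
#'
#' @param gm a [genotype_matrix()].
#' @param min_qual QUAL threshold (strict; default 20).
#' @param min_mq MQ threshold (strict; default 30).
#' @param rpbz_range inclusive RPBZ bounds (default `c(-3, 3)`).
#' @return list(gm, report) where report counts removals per rule (applied
#'   jointly; a site failing several rules is counted under each).
#' @export
filter_sites <- function(gm, min_qual = 20, min_mq = 30, rpbz_range = c(-3, 3)) {
  s <- gm$sites
  n_samples <- nrow(gm$samples)
  mean_dp <- mean(s$dp)
  keep_qual <- !is.na(s$qual) & s$qual > min_qual
  keep_dp <- !is.na(s$dp) & s$dp > n_samples & s$dp < 2 * mean_dp
  keep_mq <- !is.na(s$mq) & s$mq > min_mq
  keep_rpbz <- !is.na(s$rpbz) & s$rpbz >= rpbz_range[1] & s$rpbz <= rpbz_range[2]
  keep <- keep_qual & keep_dp & keep_mq & keep_rpbz
  report <- data.frame(
    rule = c("qual", "site_dp", "mq", "rpbz", "total_site_filters"),
    removed = c(sum(!keep_qual), sum(!keep_dp), sum(!keep_mq),
                sum(!keep_rpbz), sum(!keep)),
    stringsAsFactors = FALSE
  )
  list(gm = gm_subset(gm, sites = keep), report = report)
}

#' Mask genotypes with low per-sample depth
#'
#' Sets a genotype to missing wherever its per-sample read depth is below
#' `min_dp`; depth exactly `min_dp` is retained.
#'
#' @param gm a [genotype_matrix()] carrying a per-sample DP matrix.
#' @param min_dp minimum per-genotype depth (default 4).
#' @return The genotype matrix with low-depth genotypes masked; the number
#'   of newly masked genotypes is attached as attribute `"n_masked"`.
#' @export
mask_low_depth_genotypes <- function(gm, min_dp = 4) {
  if (is.null(gm$dp)) stop("per-sample DP matrix required for genotype masking")
  mask <- !is.na(gm$dp) & gm$dp < min_dp & !is.na(gm$geno)
  gm$geno[mask] <- NA_integer_
  attr(gm, "n_masked") <- sum(mask)
  gm
}

#' Remove individuals with low genome-wide depth
#'
#' Removes individuals whose mean read depth is below `factor` times the
#' across-individual mean, both computed before any removal. Mean depths
#' come from the sample sheet when present, otherwise from the per-sample
#' DP matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param factor fraction of the cohort mean (default 0.5).
#' @return list(gm, removed) with the ids removed.
#' @export
drop_low_depth_individuals <- function(gm, factor = 0.5) {
  depth <- gm$samples$mean_depth
  if (is.null(depth) || all(is.na(depth))) {
    if (is.null(gm$dp)) stop("no per-individual depth information available")
    depth <- rowMeans(gm$dp, na.rm = TRUE)
  }
  cutoff <- factor * mean(depth)
  removed <- gm$samples$sample[depth < cutoff]
  if (length(removed) == nrow(gm$samples)) stop("all individuals removed")
  list(
    gm = gm_subset(gm, samples = !(gm$samples$sample %in% removed)),
    removed = removed
  )
}

#' Remove sites with high missingness
#'
#' Drops sites whose missing-genotype fraction (over the currently
#' retained individuals) is strictly greater than `max_missing`.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @return The filtered genotype matrix; removal count attached as
#'   attribute `"n_removed"`.
#' @export
drop_high_missingness_sites <- function(gm, max_missing = 0.20) {
  frac <- colMeans(is.na(gm$geno))
  keep <- frac <= max_missing
  out <- gm_subset(gm, sites = keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove sites overlapping repeat intervals
#'
#' A site at 1-based position P is removed iff some BED interval `[s, e)`
#' (0-based half-open) satisfies `s <= P - 1 < e`. Overlap is computed
#' with GenomicRanges.
#'
#' @param gm a [genotype_matrix()].
#' @param bed repeat intervals (data.frame from [read_bed()] or a path).
#' @return The filtered genotype matrix; removal count attached as
#'   attribute `"n_removed"`.
#' @export
remove_repeat_overlaps <- function(gm, bed) {
  if (is.character(bed)) bed <- read_bed(bed)
  if (!nrow(bed)) {
    attr(gm, "n_removed") <- 0L
    return(gm)
  }
  mask <- GenomicRanges::GRanges(
    bed$scaffold, IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
  sites <- GenomicRanges::GRanges(
    gm$sites$scaffold, IRanges::IRanges(start = gm$sites$pos, width = 1L)
  )
  hit <- IRanges::overlapsAny(sites, mask)
  out <- gm_subset(gm, sites = !hit)
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Run the full post-calling filter chain
#'
#' Fixed order: site QC filters, per-genotype depth masking, low-depth
#' individual removal, site missingness, repeat-overlap removal. Returns
#' the filtered matrix plus a report reconciling input and output counts.
#'
#' @param gm a [genotype_matrix()].
#' @param bed repeat BED intervals (data.frame or path), or `NULL`.
#' @param min_qual,min_mq,rpbz_range see [filter_sites()].
#' @param genotype_min_dp see [mask_low_depth_genotypes()].
#' @param individual_min_depth_factor see [drop_low_depth_individuals()].
#' @param max_missing see [drop_high_missingness_sites()].
#' @return list(gm, report, removed_individuals); `report` is a
#'   data.frame of per-rule counts in application order.
#' @export
filter_chain <- function(gm, bed = NULL, min_qual = 20, min_mq = 30,
                         rpbz_range = c(-3, 3), genotype_min_dp = 4,
                         individual_min_depth_factor = 0.5,
                         max_missing = 0.20) {
  n_sites_in <- ncol(gm$geno)
  n_ind_in <- nrow(gm$geno)
  fs <- filter_sites(gm, min_qual, min_mq, rpbz_range)
  gm1 <- fs$gm
  gm2 <- if (!is.null(gm1$dp)) {
    mask_low_depth_genotypes(gm1, genotype_min_dp)
  } else gm1
  di <- drop_low_depth_individuals(gm2, individual_min_depth_factor)
  gm3 <- drop_high_missingness_sites(di$gm, max_missing)
  gm4 <- if (!is.null(bed)) remove_repeat_overlaps(gm3, bed) else gm3
  report <- rbind(
    data.frame(rule = "input_sites", removed = NA_integer_,
               remaining = n_sites_in),
    data.frame(rule = fs$report$rule, removed = fs$report$removed,
               remaining = NA_integer_),
    data.frame(rule = "genotypes_masked_low_dp",
               removed = attr(gm2, "n_masked") %||% 0L, remaining = NA_integer_),
    data.frame(rule = "individuals_low_depth", removed = length(di$removed),
               remaining = n_ind_in - length(di$removed)),
    data.frame(rule = "sites_high_missingness",
               removed = attr(gm3, "n_removed"), remaining = NA_integer_),
    data.frame(rule = "sites_repeat_overlap",
               removed = attr(gm4, "n_removed") %||% 0L,
               remaining = ncol(gm4$geno))
  )
  list(gm = gm4, report = report, removed_individuals = di$removed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
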