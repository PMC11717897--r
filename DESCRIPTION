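Package: migrascan
Title: Whole-Genome Differentiation Scans for Partial Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Windowed population-genomic differentiation scans aimed at partial
    migration: post-calling variant and individual filtering, Hudson FST, pi and
    Dxy in non-overlapping windows, per-SNV Weir-Cockerham FST, Tajima's D,
    per-scaffold Z-normalization and the delta-FST' net-differentiation
    statistic, outlier-cluster calling, Method-of-Moments kinship screening,
    genotype PCA, composite linkage disequilibrium, and a PCA/LD signature
    detector for segregating chromosomal inversions. Includes a synthetic-cohort
    generator (Balding-Nichols population structure, growth-skewed site
    frequency spectra, planted selected regions and inversions, related pairs)
    so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
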