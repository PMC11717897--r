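#!/usr/bin/env Rscript

# Stage 2: post-calling quality control.
#
# Applies the fixed filter chain to the called VCF: site QC (QUAL > 20,
# sample-count < INFO DP < 2x mean depth, MQ > 30, -3 <= RPBZ <= 3),
# per-genotype depth masking (DP < 4 -> missing), removal of individuals
# below half the cohort mean depth, removal of sites with > 20%
# missingness, and the repeat mask. Saves the filtered matrix for the
# later stages plus a per-rule attrition report.

suppressPackageStartupMessages(library(migrascan))

gm <- read_vcf("scratch/cohort/cohort.vcf", "scratch/cohort/cohort_samples.tsv")
message("read ", ncol(gm$geno), " biallelic SNVs x ", nrow(gm$geno),
        " individuals (", attr(gm, "n_dropped_records"),
        " non-biallelic records dropped)")

fc <- filter_chain(gm, bed = "scratch/cohort/cohort_repeats.bed")
print(fc$report)
message("individuals removed for low depth: ",
        paste(fc$removed_individuals, collapse = ", "))
message("retained: ", nrow(fc$gm$samples), " individuals, ",
        ncol(fc$gm$geno), " SNVs")

dir.create("results", showWarnings = FALSE)
write.table(fc$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(fc$gm, "scratch/filtered_gm.rds")  # stage handoff (scratch only)
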