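#!/usr/bin/env Rscript

# Stage 3: relatedness screening and population structure.
#
# Method-of-Moments kinship on LD-pruned genotypes; for every pair above
# kinship 0.1 the lower-depth member is excluded. Genotype PCA is run on
# the full retained cohort (population structure) and on the focal
# population alone (no phenotype clustering expected under panmixia).

suppressPackageStartupMessages(library(migrascan))

gm <- readRDS("scratch/filtered_gm.rds")

kin <- kinship_mom(ld_prune(gm))
write.table(kin, "results/kinship_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hits <- kin[kin$phi > 0.1, ]
message(nrow(hits), " pair(s) with kinship > 0.1:")
if (nrow(hits)) print(hits[, c("sample1", "sample2", "phi")])

removed <- apply_relatedness_exclusion(kin, gm$samples)
message("excluded (lower-depth member of each pair): ",
        paste(removed, collapse = ", "))
gm <- gm_subset(gm, samples = !(gm$samples$sample %in% removed))
message("final cohort: ", nrow(gm$samples), " individuals")
print(table(gm$samples$population, gm$samples$phenotype))

pc_all <- pca_genotypes(gm)
pc_focal <- pca_genotypes(gm, samples = gm_group(gm, population = "germany"))
scores <- data.frame(sample = rownames(pc_all$scores),
                     gm$samples[, c("population", "phenotype")],
                     pc_all$scores[, 1:4])
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("PC1/PC2 variance explained (all samples): ",
        paste(sprintf("%.1f%%", 100 * pc_all$varexp[1:2]), collapse = ", "))
message("PC1/PC2 variance explained (focal only): ",
        paste(sprintf("%.1f%%", 100 * pc_focal$varexp[1:2]), collapse = ", "))

saveRDS(gm, "scratch/final_gm.rds")
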