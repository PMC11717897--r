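#!/usr/bin/env Rscript

# Stage 4: windowed differentiation scan.
#
# Hudson FST / pi / Dxy and Tajima's D in 2.5 kb windows for (i) the
# between-phenotype comparison inside the focal population and (ii) the
# within-phenotype Spain-France control; per-scaffold Z-normalization;
# delta-FST' = focal FST' - control FST'; 99th-percentile outliers;
# clusters of >= 5 consecutive outlier windows (missing windows
# skipped); cluster summary table with Tajima's D contrasts; shared
# outliers with a second between-group comparison; genotype-class counts
# in the top cluster.

suppressPackageStartupMessages(library(migrascan))

gm <- readRDS("scratch/final_gm.rds")
mig <- gm_group(gm, phenotype = "migratory")
res <- gm_group(gm, phenotype = "resident")

focal <- comparison_windows(gm, mig, res)
control <- comparison_windows(gm, gm_group(gm, population = "spain"),
                              gm_group(gm, population = "france"))
message(sprintf(
  "control comparison: mean window FST %.3f (median %.3f)",
  mean(control$fst, na.rm = TRUE), median(control$fst, na.rm = TRUE)
))
message(sprintf(
  "genome-wide Tajima's D: migratory %.3f, resident %.3f",
  mean(focal$tajima_d1, na.rm = TRUE), mean(focal$tajima_d2, na.rm = TRUE)
))

w <- call_outliers(delta_fst_prime(focal, control))
cl <- call_clusters(w$flag, w$scaffold)
w$cluster <- cl
write.table(w, "results/windows.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

clusters <- summarize_clusters(w, cl)
clusters$p_tajima_d_migratory <- clusters$p_tajima_d_resident <- NA_real_
for (i in seq_len(nrow(clusters))) {
  k <- which(sprintf("%s_cluster%d", w$scaffold, cl) == clusters$cluster_id[i])
  if (sum(!is.na(w$tajima_d1[k])) >= 2) {
    clusters$p_tajima_d_migratory[i] <-
      compare_cluster_tajimas_d(w$tajima_d1[k], w$tajima_d1)$p_value
    clusters$p_tajima_d_resident[i] <-
      compare_cluster_tajimas_d(w$tajima_d2[k], w$tajima_d2)$p_value
  }
}
write.table(clusters, "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(clusters), " outlier cluster(s):")
print(clusters[order(-clusters$mean_delta_fst_prime),
               c("cluster_id", "n_windows", "mean_delta_fst_prime",
                 "mean_fst", "median_fst")])

# outlier sharing with a second between-group contrast (Spain vs Russia)
alt <- comparison_windows(gm, gm_group(gm, population = "spain"),
                          gm_group(gm, population = "russia"))
alt_w <- call_outliers(delta_fst_prime(alt, control))
shared <- shared_outlier_windows(w, alt_w, cl, call_clusters(alt_w$flag, alt_w$scaffold))
message(shared$n_shared, " outlier windows shared between the two comparisons (",
        shared$n_in_clusters, " inside clusters)")

# genotype-class composition of the strongest cluster, per phenotype group
if (nrow(clusters)) {
  top <- clusters[which.max(clusters$mean_delta_fst_prime), ]
  gc_mig <- genotype_class_counts(gm, top$scaffold, top$start, top$end, mig)
  gc_res <- genotype_class_counts(gm, top$scaffold, top$start, top$end, res)
  message(sprintf(
    "top cluster %s: het/hom-alt genotype tallies %d/%d (migratory) vs %d/%d (resident)",
    top$cluster_id, gc_mig$het_genotypes, gc_mig$hom_alt_genotypes,
    gc_res$het_genotypes, gc_res$hom_alt_genotypes
  ))
}

outl <- w[!is.na(w$flag) & w$flag == "outlier", ]
writeLines(sprintf("%s\t%d\t%d", outl$scaffold, outl$start - 1L, outl$end),
           "results/outlier_windows.bed")
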