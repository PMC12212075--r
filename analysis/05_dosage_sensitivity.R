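#!/usr/bin/env Rscript
# Y-dosage sensitivity: Pearson correlation of normalized expression with the
# number of Y chromosomes (0/1/2 across 46,XX / 46,XY / 47,XYY samples),
# selection at |r| > 0.48 & FDR < 0.01, intersection with strict-FDR DEGs.

library(aneudose)

counts <- read_matrix_tsv("results/counts_filtered.tsv")
meta <- read_tsv("results/simulated/meta.tsv")

keep <- meta$karyotype %in% c("46,XX", "46,XY", "47,XYY")
norm <- normalize_counts(counts[, meta$sample_id[keep]])
dr <- dosage_correlation(norm, meta$nY[keep])
write_tsv(dr, "results/dosage_XYY.tsv")
sens <- select_dosage_sensitive(dr)

de <- read_tsv("results/de_XYY_vs_XY.tsv")
strict <- call_degs(de, fdr = de_config()$strict_fdr)
inter <- intersect_with_degs(sens, strict$gene_id)
jsonlite::write_json(inter, "results/dosage_deg_intersection.json",
                     auto_unbox = TRUE)

cat(inter$n_sensitive, "dosage-sensitive genes;", inter$n_degs,
    "DEGs at FDR < 0.01;", inter$n_intersection, "in the intersection\n")
truth <- read_tsv("results/simulated/truth.tsv")
ts <- intersect(truth$gene_id[truth$dosage_sensitive], dr$gene_id)
cat("Recovery of construction-sensitive genes:",
    round(100 * mean(ts %in% sens), 1), "% of", length(ts), "\n")
cat("(PAR genes plateau between 46,XX and 46,XY - both have two sex\n")
cat(" chromosomes - so their attainable correlation with nY is bounded.)\n")
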