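#!/usr/bin/env Rscript
# Cross-syndrome comparison: DEGs shared between the 47,XYY vs 46,XY and
# 47,XXY vs 46,XY contrasts and their direction concordance.

library(aneudose)

counts <- read_matrix_tsv("results/counts_filtered.tsv")
meta <- read_tsv("results/simulated/meta.tsv")

de_a <- read_tsv("results/de_XYY_vs_XY.tsv")
keep <- meta$karyotype %in% c("47,XXY", "46,XY")
de_b <- nb_differential_test(counts[, meta$sample_id[keep]],
                             meta$karyotype[keep],
                             contrast = c("47,XXY", "46,XY"))
write_tsv(de_b, "results/de_XXY_vs_XY.tsv")

da <- call_degs(de_a); db <- call_degs(de_b)
sh <- shared_degs(da$gene_id, db$gene_id)
ia <- interaction_classification(sh,
                                 setNames(da$log2_fold_change, da$gene_id),
                                 setNames(db$log2_fold_change, db$gene_id))
jsonlite::write_json(c(ia[setdiff(names(ia), "classes")],
                       list(genes = as.list(ia$classes))),
                     "results/interaction_XYY_XXY.json", auto_unbox = TRUE)

cat(length(da$gene_id), "DEGs in 47,XYY vs 46,XY;", length(db$gene_id),
    "in 47,XXY vs 46,XY;", ia$total_shared, "shared\n")
cat("Concordant:", ia$concordant_up, "up +", ia$concordant_down, "down =",
    round(ia$pct_concordant, 2), "% (integer part",
    ia$pct_concordant_integer, ")\n")
cat("The shared, concordant set is the cross-syndrome signature: autosomal\n")
cat("genes responding alike to an extra Y or an extra X, plus PAR1 genes.\n")
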