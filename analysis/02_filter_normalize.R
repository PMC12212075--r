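#!/usr/bin/env Rscript
# Low-expression filtering (replicate-Jaccard threshold) and normalization
# (median-of-ratios size factors; TMM factors for comparison).

library(aneudose)

counts <- read_matrix_tsv("results/simulated/counts.tsv")
meta <- read_tsv("results/simulated/meta.tsv")

flt <- filter_low_expression(counts, meta$karyotype)
cat("Filter threshold s* =", signif(flt$s_star, 3), "; removed",
    nrow(counts) - nrow(flt$counts), "of", nrow(counts), "genes\n")

sf <- size_factors_median_of_ratios(flt$counts)
tmm <- tmm_factors(flt$counts)
cat("Size factors span", signif(min(sf), 3), "-", signif(max(sf), 3),
    "; TMM composition factors span", signif(min(tmm), 3), "-",
    signif(max(tmm), 3), "\n")

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(flt$counts, "results/counts_filtered.tsv")
write_tsv(data.frame(sample_id = names(sf), size_factor = unname(sf),
                     tmm_factor = unname(tmm[names(sf)])),
          "results/normalization_factors.tsv")
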