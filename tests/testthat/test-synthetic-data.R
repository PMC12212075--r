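test_that("expression simulation is deterministic and respects structural zeros", {
  cfg <- simulation_config(seed = 3)
  a <- simulate_expression_dataset(cfg)
  b <- simulate_expression_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  npy <- a$genes$territory == "NPY"
  no_y <- a$meta$sample_id[a$meta$nY == 0]
  expect_true(all(a$counts[npy, no_y] == 0))
  expect_true(any(a$counts[npy, a$meta$sample_id[a$meta$nY > 0]] > 0))
  # truth covers exactly the simulated gene set
  expect_setequal(a$truth$gene_id, rownames(a$counts))
})

test_that("PAR1 dosage converges to the 3/2 construction ratio", {
  # a realistic autosomal backbone keeps median-of-ratios anchored on
  # non-dosage genes, as in a real transcriptome where PARs are a tiny minority
  cfg <- simulation_config(
    karyotypes = study_karyotypes()[c("46,XY", "47,XYY")],
    patients_per_karyotype = 6, clones_per_patient = 3, seed = 21,
    genes_per_territory = c(AUTOSOME = 2000, PAR1 = 200, PAR2 = 4,
                            NPX = 20, NPY = 10, MT = 0))
  sim <- simulate_expression_dataset(cfg)
  norm <- normalize_counts(sim$counts)
  p1 <- sim$genes$territory == "PAR1"
  xyy <- sim$meta$sample_id[sim$meta$karyotype == "47,XYY"]
  xy <- sim$meta$sample_id[sim$meta$karyotype == "46,XY"]
  # per-gene ratio of karyotype means, averaged over the 200 PAR1 genes
  ratio <- mean(rowMeans(norm[p1, xyy]) / rowMeans(norm[p1, xy]))
  expect_lt(abs(ratio - 1.5) / 1.5, 0.05)
  # and the truth table says so by definition
  expect_true(all(sim$truth$fc_47XYY_vs_46XY[sim$truth$territory == "PAR1"] == 1.5))
})

test_that("allele-count generator yields the territory-determined fractions", {
  xyy <- simulate_allele_counts(karyotype_spec(1, 2),
                                c(AUTOSOME = 100, PAR1 = 150, NPX = 40, NPY = 20),
                                depth = 50, seed = 4)
  expect_equal(sort(unique(xyy$truth$true_fraction[xyy$truth$territory == "PAR1"])),
               c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_true(all(xyy$truth$true_fraction[xyy$truth$territory == "AUTOSOME"] == 0.5))
  expect_true(all(xyy$truth$true_fraction[xyy$truth$territory %in% c("NPX", "NPY")]
                  %in% c(0, 1)))
  # sample means converge to truth within 2 SE
  rec <- merge(xyy$records, xyy$truth, by = "snp_id")
  se <- sqrt(rec$true_fraction * (1 - rec$true_fraction) / 50)
  frac <- rec$ref_count / 50
  expect_true(mean(abs(frac - rec$true_fraction) <= 2 * se + 1e-12) > 0.9)
  # aggregated mean per truth level
  for (p in unique(rec$true_fraction)) {
    i <- rec$true_fraction == p
    agg_se <- sqrt(p * (1 - p) / (50 * sum(i)))
    expect_lt(abs(mean(frac[i]) - p), 2 * agg_se + 1e-12)
  }
  xy <- simulate_allele_counts(karyotype_spec(1, 1), c(PAR1 = 50), depth = 50, seed = 5)
  expect_true(all(xy$truth$true_fraction == 0.5))
  expect_error(simulate_allele_counts(karyotype_spec(2, 0), c(NPY = 10)),
               "no Y chromosome")
})

test_that("methylation generator validates blocks and plants recoverable signal", {
  bad <- data.frame(start = c(100, 300), end = c(400, 600), delta = 0.3)
  expect_error(simulate_methylation_dataset(planted_dmrs = bad), "disjoint")
  toobig <- data.frame(start = 100, end = 200, delta = 0.9)
  expect_error(simulate_methylation_dataset(background = 0.3, planted_dmrs = toobig),
               "within")
  a <- simulate_methylation_dataset(n_cpgs = 500, seed = 7)
  b <- simulate_methylation_dataset(n_cpgs = 500, seed = 7)
  expect_identical(a$cpgs, b$cpgs)
  expect_false(is.unsorted(unique(a$cpgs$pos)))
  expect_true(all(a$cpgs$methylated <= a$cpgs$total))

  # delta = 0 everywhere: group means agree within sampling error
  g <- tapply(a$cpgs$methylated / pmax(a$cpgs$total, 1), a$cpgs$group, mean)
  expect_lt(abs(g[["case"]] - g[["control"]]), 0.01)

  # planted block: CpGs inside are enriched for small p downstream
  blk <- data.frame(start = 5000, end = 5500, delta = 0.4)
  ms <- simulate_methylation_dataset(n_cpgs = 2000, planted_dmrs = blk, seed = 9)
  ct <- cpg_differential_test(ms$cpgs, c("case", "control"))
  inb <- ct$pos >= blk$start & ct$pos <= blk$end
  expect_gt(sum(inb), 10)
  expect_lt(median(ct$p_value[inb]), median(ct$p_value[!inb]) / 1e3)
})

test_that("seed sub-streams are independent per generator", {
  # adding a generator call does not perturb another stream
  e1 <- simulate_expression_dataset(simulation_config(seed = 10))
  invisible(simulate_allele_counts(karyotype_spec(1, 2), seed = 10))
  e2 <- simulate_expression_dataset(simulation_config(seed = 10))
  expect_identical(e1$counts, e2$counts)
  expect_true(substream_seed(10, "a") != substream_seed(10, "b"))
  expect_identical(substream_seed(10, "a"), substream_seed(10, "a"))
})
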