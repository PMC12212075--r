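test_that("per-CpG test flags complete separation and skips uncovered groups", {
  mk <- function(pos, grp, m, t) data.frame(chrom = "chr1", pos = pos,
                                            sample_id = paste0(grp, seq_along(m)),
                                            group = grp, methylated = m, total = t)
  cp <- rbind(mk(100, "case", c(0, 0, 0), c(30, 30, 30)),
              mk(100, "control", c(30, 30, 30), c(30, 30, 30)),
              mk(200, "case", c(10, 11, 9), c(30, 30, 30)),
              mk(200, "control", c(9, 12, 10), c(30, 30, 30)),
              mk(300, "case", c(0, 0, 0), c(0, 0, 0)),
              mk(300, "control", c(15, 14, 16), c(30, 30, 30)))
  ct <- cpg_differential_test(cp, c("case", "control"))
  expect_equal(nrow(ct), 2L)                    # pos 300 skipped
  expect_equal(attr(ct, "n_skipped"), 1L)
  expect_lt(ct$p_value[ct$pos == 100], 1e-5)
  expect_equal(ct$mean_diff[ct$pos == 100], -1)
  expect_gt(ct$p_value[ct$pos == 200], 0.1)
  expect_error(cpg_differential_test(transform(cp, methylated = total + 1)),
               "methylated > total")
})

test_that("null CpG type-I error is within 3x nominal at 1e-3", {
  ms <- simulate_methylation_dataset(n_cpgs = 20000, seed = 11)
  ct <- cpg_differential_test(ms$cpgs, c("case", "control"))
  expect_lt(mean(ct$p_value < 1e-3), 3e-3)
  expect_gt(mean(ct$p_value < 0.5), 0.25)       # not absurdly conservative
})

test_that("DMR rules: span, CpG count, merging and significant fraction", {
  mkres <- function(pos, p, d = 0.4) data.frame(chrom = "chr1", pos = pos,
                                                p_value = p, mean_diff = d)
  cfg <- dmr_config()
  # 3 significant CpGs spanning 49 bp: rejected
  expect_equal(nrow(call_dmrs(mkres(c(100, 120, 149), rep(1e-9, 3)), cfg)), 0L)
  # 3 significant CpGs spanning 60 bp: one DMR
  one <- call_dmrs(mkres(c(100, 130, 160), rep(1e-9, 3)), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_cpgs, 3L)
  expect_equal(one$direction, "hyper")
  # two passing regions 40 bp apart end up as one DMR (one run under the
  # default intra-gap; genuinely merged when the intra-gap is tightened)
  two <- call_dmrs(mkres(c(100, 130, 160, 200, 230, 260),
                         c(rep(1e-9, 3), rep(1e-9, 3))), cfg)
  expect_equal(nrow(two), 1L)
  expect_equal(two$start, 100)
  expect_equal(two$end, 260)
  tight <- dmr_config(max_intra_gap = 30)
  twob <- call_dmrs(mkres(c(100, 130, 160, 200, 230, 260), rep(1e-9, 6)), tight)
  expect_equal(nrow(twob), 1L)       # separate seeds 40 bp apart, then merged
  expect_equal(twob$end, 260)
  # regions 130 bp apart stay two DMRs
  twof <- call_dmrs(mkres(c(100, 130, 160, 290, 320, 350), rep(1e-9, 6)), cfg)
  expect_equal(nrow(twof), 2L)
  # hypo direction from negative differences
  hypo <- call_dmrs(mkres(c(100, 130, 160), rep(1e-9, 3), d = -0.4), cfg)
  expect_equal(hypo$direction, "hypo")
  # a run diluted below 50% significant CpGs over its span is dropped:
  # significant CpGs at 100 and 200 bound a 6-CpG region with 2/6 significant
  dil <- mkres(seq(100, 300, by = 20), rep(1, 11))
  dil$p_value[c(1, 6)] <- 1e-9
  expect_equal(nrow(call_dmrs(dil, cfg)), 0L)
  expect_error(call_dmrs(mkres(c(200, 100, 300), rep(1e-9, 3)), cfg), "unsorted")
})

test_that("DMR calling is idempotent and every call satisfies the config", {
  pm <- planted_meth(seed = 3, n_blocks = 6)
  ct <- cpg_differential_test(pm$ms$cpgs, c("case", "control"))
  cfg <- dmr_config()
  d1 <- call_dmrs(ct, cfg)
  d2 <- call_dmrs(ct, cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$end - d1$start >= cfg$min_length))
  expect_true(all(d1$n_cpgs >= cfg$min_cpgs))
  expect_true(all(d1$sig_fraction >= cfg$min_sig_fraction))
  expect_true(all(d1$direction == ifelse(d1$mean_diff >= 0, "hyper", "hypo")))
  # merging already-merged regions changes nothing
  merged <- aneudose:::.merge_regions(d1[, c("chrom", "start", "end")], cfg$merge_distance)
  expect_equal(merged$start, d1$start)
  expect_equal(merged$end, d1$end)
  # relaxing the locus threshold never shrinks the significant set
  sig1 <- ct$p_value < 1e-5 & abs(ct$mean_diff) >= 0.1
  sig2 <- ct$p_value < 1e-3 & abs(ct$mean_diff) >= 0.1
  expect_true(all(sig2[sig1]))
})

test_that("planted 500 bp blocks are recovered with few false calls", {
  pm <- planted_meth(seed = 1)
  ct <- cpg_differential_test(pm$ms$cpgs, c("case", "control"))
  dmrs <- call_dmrs(ct)
  expect_gte(block_recovery(dmrs, pm$blocks), 0.9)
  span_kb <- diff(range(pm$ms$cpgs$pos)) / 1e5
  expect_lte(false_dmrs(dmrs, pm$blocks) / span_kb, 1)
})

test_that("DMR annotation classifies promoter, gene body and intergenic regions", {
  genes <- assign_gene_territories(data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10000, 50000), end = c(20000, 60000), strand = c("+", "-")))
  dmrs <- data.frame(chrom = "chr1",
                     start = c(9400, 15000, 200000, 60100, 55000),
                     end = c(9600, 15100, 200100, 60300, 55100),
                     n_cpgs = 3L, n_sig_cpgs = 3L, sig_fraction = 1,
                     mean_diff = 0.3, direction = "hyper", min_p = 1e-9)
  ann <- annotate_dmrs(dmrs, genes)
  # TSS-500 of + strand gene; mid-gene; 180 kb away; TSS+? of - strand (TSS at end)
  expect_equal(ann$region_class,
               c("promoter", "gene_body", "intergenic", "promoter", "gene_body"))
  expect_equal(ann$gene_id[1], "plus")
  expect_equal(ann$gene_id[4], "minus")
})

test_that("DMR x DEG crosstab computes Haldane-corrected odds ratios", {
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      direction = character(0), region_class = character(0),
                      gene_id = character(0))
  degs <- data.frame(gene_id = "g1", direction = "up")
  out <- dmr_deg_crosstab(empty, degs)
  expect_true(is.na(out$promoter$odds_ratio))
  # constructed diagonal table (10,0;0,10): OR = 441 after correction
  d <- data.frame(region_class = "promoter",
                  gene_id = sprintf("g%02d", 1:20),
                  direction = rep(c("hyper", "hypo"), each = 10))
  dg <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   direction = rep(c("up", "down"), each = 10))
  out2 <- dmr_deg_crosstab(d, dg)
  expect_equal(out2$promoter$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  # synthetic coupling: hypermethylated promoters on downregulated genes
  set.seed(2)
  n <- 60
  expr_dir <- rep(c("down", "up"), each = n / 2)
  meth_dir <- ifelse(expr_dir == "down",
                     ifelse(runif(n) < 0.8, "hyper", "hypo"),
                     ifelse(runif(n) < 0.8, "hypo", "hyper"))
  d3 <- data.frame(region_class = "promoter", gene_id = sprintf("s%02d", 1:n),
                   direction = meth_dir)
  dg3 <- data.frame(gene_id = sprintf("s%02d", 1:n), direction = expr_dir)
  # hyper pairs with down, so the (hyper,up)-anchored OR is < 1
  or <- dmr_deg_crosstab(d3, dg3)$promoter$odds_ratio
  expect_lt(or, 1)
})

test_that("CpG table readers handle both Bismark dialects", {
  cov <- tempfile(fileext = ".cov")
  write.table(data.frame("chr1", c(100, 200), c(100, 200), c(50, 25),
                         c(15, 5), c(15, 15)),
              cov, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  a <- read_cpg_table(cov, "s1", "case", dialect = "coverage")
  expect_equal(a$methylated, c(15, 5))
  expect_equal(a$total, c(30, 20))
  cnts <- tempfile(fileext = ".tsv")
  write.table(data.frame("chr1", c(100, 200), c(15, 5), c(30, 20)),
              cnts, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  b <- read_cpg_table(cnts, "s1", "case", dialect = "counts")
  expect_equal(a$methylated, b$methylated)
  expect_equal(a$total, b$total)
})
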