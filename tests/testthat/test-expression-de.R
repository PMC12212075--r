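test_that("sample QC applies the read-count and assignment cutoffs", {
  stats <- data.frame(sample_id = c("a", "b", "c"),
                      input_reads = c(15e6, 20e6, 20e6),
                      assigned_fraction = c(0.9, 0.80, 0.70))
  expect_equal(sample_qc(stats), "b")
  expect_error(sample_qc(stats, samples = c("a", "d")), "d")
  # boundary: exactly at the cutoffs is kept
  edge <- data.frame(sample_id = "e", input_reads = 16e6, assigned_fraction = 0.75)
  expect_equal(sample_qc(edge), "e")
})

test_that("low-expression filter maximizes replicate Jaccard and matches a brute-force oracle", {
  m <- nb_matrix(20, 6, mean_log = log(50), seed = 2)
  m[1:5, ] <- 0                                   # dead genes
  m[6, ] <- c(1, 0, 1, 0, 1, 0)                   # noise gene
  groups <- rep(c("A", "B"), each = 3)
  flt <- filter_low_expression(m, groups)
  expect_false(any(rownames(flt$counts) %in% rownames(m)[1:5]))
  expect_true("g0010" %in% rownames(flt$counts))  # well-expressed gene retained

  # oracle: exhaustive grid evaluation, independently coded
  sf <- size_factors_median_of_ratios(m)
  norm <- sweep(m, 2, sf, "/")
  allpairs <- cbind(utils::combn(1:3, 2), utils::combn(4:6, 2))
  grid <- exp(seq(log(0.1), log(200), length.out = 40))
  jac <- sapply(grid, function(s) {
    mean(apply(allpairs, 2, function(p) {
      x <- norm[, p[1]] > s; y <- norm[, p[2]] > s
      if (!any(x | y)) 1 else sum(x & y) / sum(x | y)
    }))
  })
  expect_equal(flt$s_star, grid[which.max(jac)])
  expect_error(filter_low_expression(m[, 1, drop = FALSE], "A"), "2 samples")
})

test_that("median-of-ratios size factors satisfy their defining identities", {
  m <- nb_matrix(50, 3, seed = 3)
  mm <- cbind(m, m[, 1])                          # identical columns
  colnames(mm) <- c(colnames(m), "dup")
  sf <- size_factors_median_of_ratios(mm)
  expect_equal(unname(sf["s01"]), unname(sf["dup"]))
  m2 <- cbind(a = m[, 1], b = 2 * m[, 1])
  sf2 <- size_factors_median_of_ratios(m2)
  expect_equal(unname(sf2["b"] / sf2["a"]), 2)
  # direct formula re-computation on a random matrix; odd number of
  # all-positive genes so the median is a single observed ratio
  m3 <- nb_matrix(51, 6, mean_log = log(500), sdlog = 0.3, seed = 4) + 1
  geo <- exp(rowMeans(log(m3)))
  oracle <- apply(m3 / geo, 2, median)
  expect_equal(size_factors_median_of_ratios(m3), oracle)
  # equivariance: scaling one library by c scales its factor, relative to
  # any other library, by c exactly
  m4 <- m3; m4[, 2] <- m4[, 2] * 3
  s3 <- size_factors_median_of_ratios(m3)
  s4 <- size_factors_median_of_ratios(m4)
  expect_equal(unname(s4[2] / s4[1]), unname(3 * s3[2] / s3[1]))
  z <- matrix(c(0, 1, 1, 0), 2)
  expect_error(size_factors_median_of_ratios(z), "pseudo")
  expect_silent(size_factors_median_of_ratios(z, pseudo_reference = TRUE))
})

test_that("median-of-ratios equals DESeq2 and TMM equals edgeR", {
  skip_if_not_installed("DESeq2")
  skip_if_not_installed("edgeR")
  m <- nb_matrix(300, 6, seed = 11, col_factors = c(1, 1.5, 0.7, 2, 1.2, 0.9))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(row.names = colnames(m), g = factor(rep(1:2, 3))), ~g)
  expect_equal(size_factors_median_of_ratios(m),
               DESeq2::sizeFactors(DESeq2::estimateSizeFactors(dds)),
               tolerance = 1e-12)
  expect_equal(unname(tmm_factors(m)),
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-6)
})

test_that("TMM is neutral under depth scaling and recovers composition within 5%", {
  m <- nb_matrix(200, 4, seed = 5)
  ident <- m[, c(1, 1, 1, 1)]
  colnames(ident) <- sprintf("s%d", 1:4)
  expect_equal(unname(tmm_factors(ident)), rep(1, 4), tolerance = 1e-12)
  scaled <- sweep(m, 2, c(1, 2, 4, 0.5), "*")
  expect_equal(unname(tmm_factors(scaled)), rep(1, 4), tolerance = 0.02)
  # 10% of genes upregulated 6x in sample 1: the trimmed mean removes them,
  # so sample 1's factor counteracts the composition shift exactly
  m2 <- nb_matrix(100, 4, dispersion = 0.02, mean_log = log(500), seed = 6)
  extra <- sum(m2[1:10, 1]) * 5
  m2[1:10, 1] <- m2[1:10, 1] * 6
  truth1 <- 1 / (1 + extra / (sum(m2[, 1]) - extra))
  truthf <- c(truth1, 1, 1, 1)
  truthf <- truthf / exp(mean(log(truthf)))
  f <- tmm_factors(m2)
  expect_true(all(abs(f / truthf - 1) < 0.05))
})

test_that("FPKM follows its defining formula", {
  cnt <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s"))
  fp <- compute_fpkm(cnt, c(a = 1000, b = 2000), library_sizes = 1e6)
  expect_equal(unname(fp[, 1]), c(100, 50))
  expect_equal(compute_fpkm(cnt, c(a = 1000, b = 2000), library_sizes = 2e6),
               fp / 2)
  expect_error(compute_fpkm(cnt, c(a = 1000, b = 2000), library_sizes = 0),
               "library size")
  expect_error(compute_fpkm(cnt, c(a = 0, b = 2000)), "> 0")
})

test_that("NB Wald test: exact zero LFC for duplicated groups and calibrated type I error", {
  m <- nb_matrix(100, 3, seed = 7)
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("s%02d", 1:6)
  res <- nb_differential_test(dup, rep(c("A", "B"), each = 3), contrast = c("A", "B"))
  expect_true(all(res$log2_fold_change == 0))
  expect_error(nb_differential_test(m[, 1:3], c("A", "A", "B")), ">= 2 samples")

  # Monte-Carlo null: 20 reps, 500 genes, 4 vs 4, alpha within [0.03, 0.07]
  set.seed(99)
  rates <- replicate(20, {
    mu <- rlnorm(500, log(100), 1)
    cnt <- matrix(rnbinom(500 * 8, mu = rep(mu, 8), size = 1 / 0.05), nrow = 500)
    rownames(cnt) <- sprintf("g%03d", 1:500)
    colnames(cnt) <- sprintf("s%02d", 1:8)
    de <- nb_differential_test(cnt, rep(c("A", "B"), each = 4), contrast = c("A", "B"))
    mean(de$p_value < 0.05)
  })
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("NB Wald test detects planted 1.5-fold genes and controls realized FDP", {
  set.seed(7)
  mu <- rlnorm(400, log(300), 0.5)
  fc <- rep(1, 400); fc[1:20] <- 1.5; fc[21:40] <- 1 / 1.5
  cnt <- cbind(matrix(rnbinom(400 * 6, mu = rep(mu * fc, 6), size = 50), nrow = 400),
               matrix(rnbinom(400 * 6, mu = rep(mu, 6), size = 50), nrow = 400))
  rownames(cnt) <- sprintf("g%03d", 1:400)
  colnames(cnt) <- sprintf("s%02d", 1:12)
  de <- nb_differential_test(cnt, rep(c("A", "B"), each = 6), contrast = c("A", "B"))
  planted <- sprintf("g%03d", 1:40)
  hits <- de$gene_id[de$fdr < 0.05]
  expect_gt(mean(planted %in% hits), 0.5)     # majority detected
  fdp <- mean(!(hits %in% planted))
  expect_lte(fdp, 0.10)                       # <= 2x nominal FDR
})

test_that("BH adjustment is monotone and DEG calling applies both thresholds", {
  set.seed(12)
  m <- nb_matrix(200, 8, seed = 12)
  res <- nb_differential_test(m, rep(c("A", "B"), each = 4), contrast = c("A", "B"))
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-15))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))

  fake <- data.frame(gene_id = c("a", "b", "c"),
                     log2_fold_change = c(0.60, 0.50, 2.0),
                     fdr = c(0.04, 0.04, 0.06))
  deg <- call_degs(fake)
  expect_equal(deg$gene_id, "a")
  expect_equal(deg$direction, "up")

  # DEG set invariant under gene-row permutation
  perm <- sample(nrow(m))
  res2 <- nb_differential_test(m[perm, ], rep(c("A", "B"), each = 4),
                               contrast = c("A", "B"))
  expect_equal(call_degs(res)$gene_id, call_degs(res2)$gene_id)
  expect_equal(res$p_value, res2$p_value[match(res$gene_id, res2$gene_id)])
})
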