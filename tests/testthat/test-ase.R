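test_that("allelic fractions and status classification follow the thresholds", {
  af <- allelic_fraction(c(30, 60, 20, 0), c(30, 0, 40, 0))
  expect_equal(af$fraction, c(0.5, 1, 1 / 3, NA))
  expect_equal(af$depth, c(60, 60, 60, 0))
  expect_error(allelic_fraction(-1, 5), "negative")

  expect_equal(classify_snp_expression(0.33, 60), "BIALLELIC")
  expect_equal(classify_snp_expression(0.02, 60), "MONOALLELIC")
  expect_equal(classify_snp_expression(0.5, 5), "LOW_COVERAGE")
  # boundary: minor share exactly at threshold is biallelic
  expect_equal(classify_snp_expression(0.10, 10), "BIALLELIC")
})

test_that("fraction symmetry: swapping ref and alt mirrors the fraction, keeps status", {
  set.seed(3)
  ref <- rbinom(200, 50, runif(200))
  alt <- 50 - ref
  a <- allelic_fraction(ref, alt)
  b <- allelic_fraction(alt, ref)
  expect_equal(b$fraction, 1 - a$fraction)
  expect_equal(classify_snp_expression(a$fraction, a$depth),
               classify_snp_expression(b$fraction, b$depth))
})

test_that("PAR SNPs are reported on X; NPY SNPs stay on Y flagged hemizygous", {
  pa <- par_assignment(c("chrY", "chrX", "chrY", "chr5"),
                       c(1400000, 5e6, 6e6, 1000))
  expect_equal(pa$assigned_chrom, c("chrX", "chrX", "chrY", "chr5"))
  expect_equal(pa$territory, c("PAR1", "NPX", "NPY", "AUTOSOME"))
  expect_equal(pa$hemizygous, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("cluster summary separates karyotype-specific allelic modes", {
  # 46,XY PAR1: single cluster near 50%
  xy <- simulate_allele_counts(karyotype_spec(1, 1), c(PAR1 = 200), depth = 50,
                               seed = 42)
  cs <- cluster_summary(xy$records$ref_count,
                        xy$records$ref_count + xy$records$alt_count)
  expect_equal(cs$n_modes, 1L)
  expect_lt(abs(cs$centers - 0.5), 0.015)

  # 47,XYY PAR1: two clusters near 1/3 and 2/3
  xyy <- simulate_allele_counts(karyotype_spec(1, 2), c(PAR1 = 200), depth = 50,
                                seed = 6)
  cs2 <- cluster_summary(xyy$records$ref_count,
                         xyy$records$ref_count + xyy$records$alt_count)
  expect_equal(cs2$n_modes, 2L)
  expect_lt(abs(cs2$centers[1] - 1 / 3), 0.03)
  expect_lt(abs(cs2$centers[2] - 2 / 3), 0.03)

  # all-monoallelic group: centers at the extremes
  mono <- simulate_allele_counts(karyotype_spec(1, 1), c(NPX = 100), depth = 50,
                                 seed = 7)
  cs3 <- cluster_summary(mono$records$ref_count,
                         mono$records$ref_count + mono$records$alt_count)
  expect_equal(cs3$n_modes, 2L)
  expect_lt(cs3$centers[1], 0.05)
  expect_gt(cs3$centers[2], 0.95)

  few <- cluster_summary(rbinom(5, 50, 0.5), rep(50, 5))
  expect_true(few$insufficient)
  expect_equal(few$n_modes, 0L)
})

test_that("biallelic calls outside the PARs stay within the binomial false-call rate", {
  sim <- simulate_allele_counts(karyotype_spec(1, 2),
                                c(AUTOSOME = 50, PAR1 = 50, NPX = 300, NPY = 300),
                                depth = 50, seed = 9)
  calls <- ase_calls(sim$records)
  sexnp <- calls$territory %in% c("NPX", "NPY")
  # false biallelic call needs >= 5 minor reads at error-free simulation: rate 0
  implied <- 2 * pbinom(ceiling(0.10 * 50) - 1, 50, 0, lower.tail = FALSE)
  expect_lte(mean(calls$status[sexnp] == "BIALLELIC"), implied)
  # and PAR1 calls in 47,XYY are overwhelmingly biallelic
  expect_gt(mean(calls$status[calls$territory == "PAR1"] == "BIALLELIC"), 0.95)
})

test_that("allele-count tables round-trip through the VCF-like TSV reader", {
  sim <- simulate_allele_counts(karyotype_spec(1, 2), c(PAR1 = 20), seed = 2)
  f <- tempfile(fileext = ".tsv")
  df <- sim$records
  names(df) <- c("SNP_ID", "GENE_ID", "CHROM", "POS", "SAMPLE",
                 "REF_COUNT", "ALT_COUNT", "TERRITORY")
  write_tsv(df, f)
  back <- read_allele_counts(f)
  expect_equal(back$ref_count, sim$records$ref_count)
  expect_equal(back$chrom, sim$records$chrom)
  calls <- ase_calls(back)
  expect_true(all(calls$assigned_chrom == "chrX"))
})
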