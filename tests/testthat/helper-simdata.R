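# shared fixtures built in code

# small NB count matrix with optional per-column scaling
nb_matrix <- function(n_genes, n_samples, mean_log = log(150), sdlog = 1,
                      dispersion = 0.1, col_factors = rep(1, n_samples),
                      seed = 1) {
  set.seed(seed)
  mu <- rlnorm(n_genes, mean_log, sdlog)
  m <- sapply(seq_len(n_samples), function(j)
    rnbinom(n_genes, mu = mu * col_factors[j], size = 1 / dispersion))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}

# two-karyotype expression world used by DE/bootstrap tests
small_cohort <- function(seed = 8, patients = 5, clones = 3,
                         lfc = 1.5, baseline = 200) {
  simulate_expression_dataset(simulation_config(
    karyotypes = study_karyotypes()[c("46,XY", "47,XYY")],
    patients_per_karyotype = patients, clones_per_patient = clones,
    baseline_mean = baseline, autosomal_deg_log2fc = lfc, seed = seed,
    genes_per_territory = c(AUTOSOME = 150, PAR1 = 25, PAR2 = 4,
                            NPX = 30, NPY = 10, MT = 0)))
}

# planted methylation world at the stated scale: 500 bp blocks, delta 0.4,
# depth 30, 3 vs 3
planted_meth <- function(seed, n_blocks = 10) {
  blocks <- data.frame(start = seq(20000, by = 20000, length.out = n_blocks),
                       end = seq(20500, by = 20000, length.out = n_blocks),
                       delta = 0.4)
  ms <- simulate_methylation_dataset(n_cpgs = 8000, planted_dmrs = blocks,
                                     seed = seed)
  list(ms = ms, blocks = blocks)
}

# fraction of truth blocks matched by a called DMR at >= 50% reciprocal overlap
block_recovery <- function(dmrs, blocks) {
  mean(vapply(seq_len(nrow(blocks)), function(i) {
    if (!nrow(dmrs)) return(FALSE)
    ov <- pmin(dmrs$end, blocks$end[i]) - pmax(dmrs$start, blocks$start[i])
    any(pmin(ov / (dmrs$end - dmrs$start),
             ov / (blocks$end[i] - blocks$start[i])) >= 0.5)
  }, logical(1)))
}

# DMRs not touching any truth block
false_dmrs <- function(dmrs, blocks) {
  if (!nrow(dmrs)) return(0L)
  sum(vapply(seq_len(nrow(dmrs)), function(j)
    all(pmin(dmrs$end[j], blocks$end) - pmax(dmrs$start[j], blocks$start) <= 0),
    logical(1)))
}
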