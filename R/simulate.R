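# synthetic aneuploid karyotype data: NB expression with patient-clone
# hierarchy, binomial allele counts, beta-binomial CpG methylation

#' Karyotype specification
#'
#' @param nX Number of X chromosomes (>= 1).
#' @param nY Number of Y chromosomes (>= 0).
#' @param label Karyotype string, e.g. `"47,XYY"`.
#' @return A `karyotype_spec` list.
#' @export
karyotype_spec <- function(nX, nY, label = NULL) {
  stopifnot(nX >= 1, nY >= 0)
  if (is.null(label))
    label <- paste0(nX + nY + 44, ",", strrep("X", nX), strrep("Y", nY))
  structure(list(nX = as.integer(nX), nY = as.integer(nY), label = label),
            class = "karyotype_spec")
}

#' The four study karyotypes
#' @return Named list of [karyotype_spec()]: 46,XY; 47,XYY; 47,XXY; 46,XX.
#' @export
study_karyotypes <- function() {
  ks <- list(karyotype_spec(1, 1), karyotype_spec(1, 2),
             karyotype_spec(2, 1), karyotype_spec(2, 0))
  names(ks) <- vapply(ks, `[[`, character(1), "label")
  ks
}

#' Simulation configuration
#'
#' Defaults state the simulated world once: negative-binomial counts with
#' gene-level baselines around `baseline_mean`, dispersion 0.05 (typical bulk
#' RNA-seq), a per-patient per-gene log-normal random effect of sd 0.1 shared
#' by that patient's clones (the clonal correlation the bootstrap exists for),
#' PAR means scaling with (nX+nY)/2, NPY means with nY (structural zeros at
#' nY = 0), and a 0.8 multiplicative NPX compensation per extra Y on a subset
#' of NPX genes. 10% of autosomal genes are planted DEGs (|log2FC| = 1) in
#' supernumerary karyotypes, concordant between 47,XYY and 47,XXY.
#'
#' @param karyotypes List of [karyotype_spec()] to simulate.
#' @param patients_per_karyotype,clones_per_patient Cohort layout (recycled
#'   over karyotypes); ignored when `design` is given.
#' @param design Optional explicit data.frame(karyotype, patient, clone)
#'   overriding the balanced layout.
#' @param genes_per_territory Named integer vector over
#'   AUTOSOME/PAR1/PAR2/NPX/NPY/MT.
#' @param baseline_mean Median of the log-normal gene baseline means (counts).
#' @param baseline_sdlog Spread of gene baselines on the log scale.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param patient_sd sdlog of the patient-by-gene random effect.
#' @param clone_sd sdlog of residual clone-level depth noise.
#' @param npx_compensation Multiplicative factor per extra Y applied to the
#'   compensated NPX subset (invented magnitude, documented as such).
#' @param npx_compensated_fraction Fraction of NPX genes subject to it.
#' @param fraction_true_deg_autosomal Fraction of autosomal genes planted DE.
#' @param autosomal_deg_log2fc Absolute planted log2 fold change.
#' @param library_size Expected total counts per sample.
#' @param cell_type Label stored in the metadata.
#' @param seed Integer global seed; all sub-streams derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(karyotypes = study_karyotypes(),
                              patients_per_karyotype = 3L,
                              clones_per_patient = 3L,
                              design = NULL,
                              genes_per_territory = c(AUTOSOME = 300L, PAR1 = 25L,
                                                      PAR2 = 4L, NPX = 60L,
                                                      NPY = 12L, MT = 13L),
                              baseline_mean = 100,
                              baseline_sdlog = 1,
                              nb_dispersion = 0.05,
                              patient_sd = 0.1,
                              clone_sd = 0.05,
                              npx_compensation = 0.8,
                              npx_compensated_fraction = 0.25,
                              fraction_true_deg_autosomal = 0.1,
                              autosomal_deg_log2fc = 1,
                              library_size = 1e6,
                              cell_type = "iPSC",
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(baseline_mean > 0, nb_dispersion > 0, npx_compensation > 0,
            fraction_true_deg_autosomal >= 0, fraction_true_deg_autosomal <= 1,
            library_size > 0, all(genes_per_territory >= 0))
  if (inherits(cfg$karyotypes, "karyotype_spec")) cfg$karyotypes <- list(cfg$karyotypes)
  structure(cfg, class = "simulation_config")
}

# synthetic gene table: coordinates placed inside the right territory intervals
.simulate_genes <- function(n_per, tmap = territory_map()) {
  place <- function(n, chrom, lo, hi, prefix) {
    if (n == 0L) return(NULL)
    gap <- (hi - lo) / (n + 1)
    start <- floor(lo + gap * seq_len(n))
    len <- pmin(floor(gap * 0.5) + 200, round(stats::rlnorm(n, log(3000), 0.5)) + 200)
    data.frame(gene_id = sprintf("%s_%03d", prefix, seq_len(n)), chrom = chrom,
               start = start, end = start + len, strand = "+",
               stringsAsFactors = FALSE)
  }
  g <- rbind(
    place(n_per[["AUTOSOME"]], "chr2", 1e5, 2.4e8, "AUT"),
    place(n_per[["PAR1"]], "chrX", tmap$par1_x[1] + 1e4, tmap$par1_x[2] - 1e3, "PAR1"),
    place(n_per[["PAR2"]], "chrX", tmap$par2_x[1] + 1e3, tmap$par2_x[2] - 1e3, "PAR2"),
    place(n_per[["NPX"]], "chrX", tmap$par1_x[2] + 1e6, tmap$par2_x[1] - 1e6, "NPX"),
    place(n_per[["NPY"]], "chrY", tmap$par1_y[2] + 1e6, tmap$par2_y[1] - 1e6, "NPY"),
    place(n_per[["MT"]], "chrM", 1, 16500, "MT"))
  assign_gene_territories(g, tmap)
}

.balanced_design <- function(cfg) {
  ks <- cfg$karyotypes
  npat <- rep_len(cfg$patients_per_karyotype, length(ks))
  ncl <- rep_len(cfg$clones_per_patient, length(ks))
  rows <- list()
  for (i in seq_along(ks)) {
    lab <- ks[[i]]$label
    for (p in seq_len(npat[i])) {
      pid <- sprintf("%s_P%d", gsub("[^0-9XY]", "", lab), p)
      rows[[length(rows) + 1L]] <- data.frame(
        karyotype = lab, patient = pid,
        clone = sprintf("%s_c%d", pid, seq_len(ncl[i])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a karyotype-structured expression dataset
#'
#' Draws gene baselines, applies the territory dosage model per karyotype,
#' multiplies in a patient-by-gene log-normal random effect shared by a
#' patient's clones, scales to the target library size with clone-level noise,
#' and samples negative-binomial counts. NPY rows are structural zeros in
#' karyotypes without a Y. Fixed seed gives bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (integer gene x sample matrix), `meta`
#'   (sample metadata: sample_id, patient, clone, cell_type, karyotype, nX,
#'   nY), `genes` (GeneRecord data.frame), `truth` (per-gene true fold
#'   changes per contrast and the per-extra-Y log2 dosage slope), and the
#'   config.
#' @export
simulate_expression_dataset <- function(config = simulation_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(substream_seed(cfg$seed, "expression/genes"))
  genes <- .simulate_genes(cfg$genes_per_territory)
  G <- nrow(genes)
  base <- stats::rlnorm(G, log(cfg$baseline_mean), cfg$baseline_sdlog)

  # planted autosomal DEGs: concordant in every supernumerary karyotype
  aut <- which(genes$territory == "AUTOSOME")
  n_deg <- round(length(aut) * cfg$fraction_true_deg_autosomal)
  deg_idx <- if (n_deg > 0) sample(aut, n_deg) else integer(0)
  deg_sign <- sample(c(1, -1), length(deg_idx), replace = TRUE)
  lfc_deg <- numeric(G)
  lfc_deg[deg_idx] <- deg_sign * cfg$autosomal_deg_log2fc

  npx <- which(genes$territory == "NPX")
  n_comp <- round(length(npx) * cfg$npx_compensated_fraction)
  comp_idx <- if (n_comp > 0) sample(npx, n_comp) else integer(0)

  # expected mean multiplier per gene for a karyotype, relative to 46,XY
  dose_mult <- function(k) {
    m <- rep(1, G)
    tot <- k$nX + k$nY
    m[genes$territory %in% c("PAR1", "PAR2")] <- tot / 2
    m[genes$territory == "NPY"] <- k$nY
    if (k$nY > 1) m[comp_idx] <- cfg$npx_compensation^(k$nY - 1)
    if (tot > 2) m[deg_idx] <- 2^lfc_deg[deg_idx]
    m
  }

  design <- if (!is.null(cfg$design)) cfg$design else .balanced_design(cfg)
  stopifnot(all(c("karyotype", "patient", "clone") %in% names(design)))
  klab <- vapply(cfg$karyotypes, `[[`, character(1), "label")
  if (!all(design$karyotype %in% klab))
    stop("design contains karyotypes absent from config: ",
         paste(setdiff(design$karyotype, klab), collapse = ", "))

  patients <- unique(design$patient)
  set.seed(substream_seed(cfg$seed, "expression/patient_effects"))
  pat_eff <- matrix(stats::rlnorm(length(patients) * G, 0, cfg$patient_sd),
                    nrow = G, dimnames = list(genes$gene_id, patients))

  n <- nrow(design)
  counts <- matrix(0L, G, n, dimnames = list(genes$gene_id, design$clone))
  set.seed(substream_seed(cfg$seed, "expression/counts"))
  for (j in seq_len(n)) {
    k <- cfg$karyotypes[[match(design$karyotype[j], klab)]]
    mu <- base * dose_mult(k) * pat_eff[, design$patient[j]]
    sf <- cfg$library_size / sum(mu) * stats::rlnorm(1, 0, cfg$clone_sd)
    mu <- mu * sf
    counts[, j] <- ifelse(mu <= 0, 0L,
                          stats::rnbinom(G, mu = mu, size = 1 / cfg$nb_dispersion))
  }

  meta <- data.frame(sample_id = design$clone, patient = design$patient,
                     clone = design$clone, cell_type = cfg$cell_type,
                     karyotype = design$karyotype,
                     nX = vapply(design$karyotype,
                                 function(l) cfg$karyotypes[[match(l, klab)]]$nX, integer(1)),
                     nY = vapply(design$karyotype,
                                 function(l) cfg$karyotypes[[match(l, klab)]]$nY, integer(1)),
                     stringsAsFactors = FALSE, row.names = NULL)

  ref <- karyotype_spec(1, 1)
  fc_vs_ref <- function(k) dose_mult(k) / dose_mult(ref)
  truth <- data.frame(gene_id = genes$gene_id, territory = genes$territory,
                      stringsAsFactors = FALSE)
  for (k in cfg$karyotypes) {
    if (k$label == ref$label) next
    truth[[paste0("fc_", gsub(",", "", k$label), "_vs_46XY")]] <- fc_vs_ref(k)
  }
  # per-extra-Y log2 slope holding nX = 1 (NPY: 2 copies vs 1)
  slope <- rep(0, G)
  slope[genes$territory %in% c("PAR1", "PAR2")] <- log2(3 / 2)
  slope[genes$territory == "NPY"] <- 1
  slope[comp_idx] <- log2(cfg$npx_compensation)
  truth$dosage_slope <- slope
  truth$dosage_sensitive <- slope != 0

  list(counts = counts, meta = meta, genes = genes, truth = truth, config = cfg)
}

#' Simulate per-SNP allele counts for a karyotype
#'
#' Heterozygous autosomal SNPs draw reference reads Binomial(depth, 1/2). A
#' PAR1/PAR2 SNP where the X allele differs from the (identical) Y alleles has
#' X-allele fraction `wX nX / (wX nX + wY nY)` - 1/2 in 46,XY, 1/3 or 2/3 in
#' 47,XYY (which allele is "reference" is chosen at random per SNP). NPX and
#' NPY SNPs are monoallelic (fraction 0 or 1); NPY SNPs require a Y.
#'
#' @param karyotype A [karyotype_spec()].
#' @param n_snps_per_territory Named vector over AUTOSOME/PAR1/NPX/NPY.
#' @param depth Reads per SNP (fixed; default 50).
#' @param x_weight,y_weight Per-chromosome expression weights (equal by
#'   default; a knob for Y-allele under-expression or mapping bias).
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @return List with `records` (snp_id, gene_id, chrom, pos, sample_id,
#'   ref_count, alt_count, territory) and `truth` (snp_id, territory,
#'   true_fraction: expected reference-allele share).
#' @export
simulate_allele_counts <- function(karyotype, n_snps_per_territory = c(AUTOSOME = 200L,
                                     PAR1 = 50L, NPX = 50L, NPY = 20L),
                                   depth = 50L, x_weight = 1, y_weight = 1,
                                   n_samples = 1L, seed = 1L) {
  stopifnot(inherits(karyotype, "karyotype_spec"), depth >= 1)
  k <- karyotype
  np <- n_snps_per_territory
  n_per <- function(t) if (t %in% names(np)) np[[t]] else 0L
  if (k$nY == 0 && n_per("NPY") > 0)
    stop("karyotype ", k$label, " has no Y chromosome: cannot simulate NPY SNPs")
  set.seed(substream_seed(seed, paste0("ase/", k$label)))
  tmap <- territory_map()
  recs <- list()
  truths <- list()
  mk <- function(terr, n, chrom, lo, hi, p_fun) {
    if (is.na(n) || n == 0) return()
    pos <- sort(sample(seq(lo, hi), n))
    p <- p_fun(n)
    snp <- sprintf("%s_snp%04d", terr, seq_len(n))
    for (s in seq_len(n_samples)) {
      ref <- stats::rbinom(n, depth, p)
      recs[[length(recs) + 1L]] <<- data.frame(
        snp_id = snp, gene_id = sprintf("%s_gene%04d", terr, seq_len(n)),
        chrom = chrom, pos = pos, sample_id = sprintf("S%02d", s),
        ref_count = ref, alt_count = depth - ref, territory = terr,
        stringsAsFactors = FALSE)
    }
    truths[[length(truths) + 1L]] <<- data.frame(
      snp_id = snp, territory = terr, true_fraction = p, stringsAsFactors = FALSE)
  }
  x_frac <- (x_weight * k$nX) / (x_weight * k$nX + y_weight * k$nY)
  par_p <- function(n) {
    if (k$nY == 0 || (k$nX + k$nY == 2 && k$nY == 1)) {
      rep(0.5, n)           # 46,XY (X vs Y) and 46,XX (X1 vs X2) het SNPs
    } else {
      ifelse(stats::runif(n) < 0.5, x_frac, 1 - x_frac)
    }
  }
  mono_p <- function(n) ifelse(stats::runif(n) < 0.5, 0, 1)
  mk("AUTOSOME", n_per("AUTOSOME"), "chr2", 1e5, 2.4e8, function(n) rep(0.5, n))
  mk("PAR1", n_per("PAR1"), "chrX", tmap$par1_x[1] + 1, tmap$par1_x[2] - 1, par_p)
  mk("NPX", n_per("NPX"), "chrX", tmap$par1_x[2] + 1e6, tmap$par2_x[1] - 1e6, mono_p)
  if (n_per("NPY") > 0 && k$nY > 0)
    mk("NPY", n_per("NPY"), "chrY", tmap$par1_y[2] + 1e6, tmap$par2_y[1] - 1e6, mono_p)
  list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
}

#' Simulate a CpG methylation dataset with planted DMR blocks
#'
#' CpG positions are laid down with geometric spacing at CpG-island-like
#' density (RRBS enriches CpG-dense fragments; default mean spacing 25 bp);
#' methylated counts are beta-binomial around a background level, shifted by
#' `delta` inside planted blocks for the case group. The default replicate
#' overdispersion (0.01) reflects clonal cell lines.
#'
#' @param n_cpgs Number of CpG sites.
#' @param n_per_group Samples per group (case, control).
#' @param depth Mean per-CpG coverage (Poisson, floored at 1).
#' @param background Background methylation level in [0,1].
#' @param rho Beta-binomial overdispersion in (0,1).
#' @param planted_dmrs data.frame(chrom, start, end, delta) of disjoint
#'   blocks; `background + delta` must stay in [0,1].
#' @param mean_spacing Mean background CpG spacing in bp.
#' @param min_spacing Minimum CpG spacing in bp; RRBS coverage is contiguous
#'   within CpG-dense MspI fragments, so spacing is floored rather than
#'   purely geometric.
#' @param island_spacing CpG spacing inside planted blocks: DMRs sit in
#'   CpG-island-like regions, which are denser than background.
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @return List with `cpgs` (long table: chrom, pos, sample_id, group,
#'   methylated, total) and `truth` (the planted block table).
#' @export
simulate_methylation_dataset <- function(n_cpgs = 2000L, n_per_group = 3L,
                                         depth = 30, background = 0.3,
                                         rho = 0.01,
                                         planted_dmrs = NULL,
                                         mean_spacing = 25, min_spacing = 10,
                                         island_spacing = 12,
                                         chrom = "chr2", seed = 1L) {
  stopifnot(background >= 0, background <= 1, rho > 0, rho < 1,
            mean_spacing > min_spacing)
  if (!is.null(planted_dmrs) && nrow(planted_dmrs) > 1) {
    o <- order(planted_dmrs$start)
    b <- planted_dmrs[o, ]
    if (any(b$start[-1] < b$end[-nrow(b)]))
      stop("planted DMR blocks must be disjoint")
  }
  if (!is.null(planted_dmrs) &&
      any(background + planted_dmrs$delta < 0 | background + planted_dmrs$delta > 1))
    stop("background + delta must stay within [0, 1]")
  set.seed(substream_seed(seed, "methylation"))
  pos <- cumsum(stats::rgeom(n_cpgs, 1 / (mean_spacing - min_spacing + 1)) +
                  min_spacing) + 1000L
  if (!is.null(planted_dmrs)) {
    island <- unlist(lapply(seq_len(nrow(planted_dmrs)), function(i)
      seq(planted_dmrs$start[i], planted_dmrs$end[i], by = island_spacing)))
    pos <- sort(unique(c(pos, round(island))))
  }
  n_cpgs <- length(pos)
  p_ctrl <- rep(background, n_cpgs)
  p_case <- p_ctrl
  if (!is.null(planted_dmrs)) {
    for (i in seq_len(nrow(planted_dmrs))) {
      inb <- pos >= planted_dmrs$start[i] & pos <= planted_dmrs$end[i]
      p_case[inb] <- background + planted_dmrs$delta[i]
    }
  }
  draw <- function(p, sample_id, group) {
    tot <- pmax(1L, stats::rpois(n_cpgs, depth))
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    pr <- stats::rbeta(n_cpgs, pmax(a, 1e-8), pmax(b, 1e-8))
    pr[p == 0] <- 0; pr[p == 1] <- 1
    data.frame(chrom = chrom, pos = pos, sample_id = sample_id, group = group,
               methylated = stats::rbinom(n_cpgs, tot, pr), total = tot,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (s in seq_len(n_per_group))
    out[[length(out) + 1L]] <- draw(p_case, sprintf("case_%d", s), "case")
  for (s in seq_len(n_per_group))
    out[[length(out) + 1L]] <- draw(p_ctrl, sprintf("ctrl_%d", s), "control")
  list(cpgs = do.call(rbind, out),
       truth = if (is.null(planted_dmrs))
         data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    delta = numeric(0))
       else cbind(planted_dmrs, chrom = if (is.null(planted_dmrs$chrom)) chrom
                  else planted_dmrs$chrom)[c("chrom", "start", "end", "delta")])
}

#' Write every synthetic table to a directory
#'
#' Emits counts.tsv, meta.tsv, genes.bed, truth.tsv for an expression
#' simulation; companion writers for allele counts and CpG tables.
#'
#' @param sim Result of [simulate_expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_expression_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv(sim$meta, file.path(dir, "meta.tsv"))
  write_bed_annotation(sim$genes, file.path(dir, "genes.bed"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
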