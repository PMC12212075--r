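# config-driven workflow: simulate/load -> qc -> filter -> normalize -> de ->
# {dosage, bootstrap, profile, concord}; ase and methylation independent

#' Workflow configuration
#'
#' Either a path to a JSON file or an R list. Recognized fields: `seed`,
#' `counts`, `meta` (paths; omitted means simulate with
#' [simulation_config()] defaults), `contrast` (case/control karyotypes),
#' `contrast_b` (second contrast for the concordance stage), `stages`
#' (character subset of de, dosage, bootstrap, profile, concord, ase,
#' methylation), `fdr`, `lfc`, `span`, `n_iter`.
#'
#' @param config List or JSON path.
#' @return Normalized config list.
#' @export
workflow_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(seed = 1L, counts = NULL, meta = NULL,
                   contrast = c("47,XYY", "46,XY"),
                   contrast_b = c("47,XXY", "46,XY"),
                   stages = c("de", "dosage", "bootstrap", "profile",
                              "concord", "ase", "methylation"),
                   fdr = 0.05, lfc = 0.58, span = 0.45, n_iter = 50L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the dosage-analysis workflow
#'
#' Executes the configured stages in dependency order on simulated (or
#' loaded) data, writes one TSV/JSON per stage into `out_dir`, and a
#' `manifest.json` with the R version, package version, seed and a content
#' hash of the resolved config. Deterministic given (inputs, seed); outputs
#' are sorted by gene id or coordinate for diff-stability.
#'
#' @param config See [workflow_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_workflow <- function(config = list(), out_dir = tempfile("aneudose_run_")) {
  cfg <- workflow_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("workflow stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list()

  if (!is.null(cfg$counts)) {
    if (!file.exists(cfg$counts)) stop("counts file not found: ", cfg$counts)
    if (!file.exists(cfg$meta)) stop("meta file not found: ", cfg$meta)
    counts <- read_matrix_tsv(cfg$counts)
    meta <- read_tsv(cfg$meta)
    genes <- NULL; truth <- NULL
  } else {
    sim <- stage("simulate", simulate_expression_dataset(
      simulation_config(seed = cfg$seed)))
    counts <- sim$counts; meta <- sim$meta; genes <- sim$genes; truth <- sim$truth
    write_expression_dataset(sim, file.path(out_dir, "simulated"))
  }

  dec <- de_config(fdr_threshold = cfg$fdr, lfc_threshold = cfg$lfc)
  flt <- stage("filter", filter_low_expression(counts, meta$karyotype))
  counts_f <- flt$counts
  sf <- stage("normalize", size_factors_median_of_ratios(counts_f))
  norm <- normalize_counts(counts_f, sf)

  in_contrast <- meta$karyotype %in% cfg$contrast
  de_a <- NULL
  if ("de" %in% cfg$stages) {
    de_a <- stage("de", nb_differential_test(
      counts_f[, in_contrast, drop = FALSE], meta$karyotype[in_contrast],
      contrast = cfg$contrast, config = dec))
    write_tsv(de_a, file.path(out_dir, "de.tsv"))
    res$de <- de_a
  }
  if ("dosage" %in% cfg$stages) {
    dr <- stage("dosage", dosage_correlation(norm, meta$nY[match(colnames(norm),
                                                                meta$sample_id)]))
    write_tsv(dr, file.path(out_dir, "dosage.tsv"))
    res$dosage <- dr
    if (!is.null(de_a)) {
      inter <- intersect_with_degs(select_dosage_sensitive(dr),
                                   call_degs(de_a, dec, fdr = dec$strict_fdr)$gene_id)
      jsonlite::write_json(inter, file.path(out_dir, "dosage_deg_intersection.json"),
                           auto_unbox = TRUE)
      res$dosage_deg_intersection <- inter
    }
  }
  if ("bootstrap" %in% cfg$stages) {
    bs <- stage("bootstrap", bootstrap_deg_stability(
      counts_f, meta, cfg$contrast, n_iter = cfg$n_iter, config = dec,
      seed = cfg$seed))
    write_tsv(bs, file.path(out_dir, "stability.tsv"))
    res$bootstrap <- bs
  }
  if ("profile" %in% cfg$stages && !is.null(genes)) {
    fpkm <- compute_fpkm(counts_f, stats::setNames(genes$length, genes$gene_id))
    pr <- stage("profile", group_profile(
      fpkm, meta, genes, group = cfg$contrast[1],
      config = profile_config(span = cfg$span,
                              reference_group = cfg$contrast[2])))
    write_tsv(pr, file.path(out_dir, "profile_chrX.tsv"))
    res$profile <- pr
  }
  if ("concord" %in% cfg$stages && !is.null(de_a) &&
      all(cfg$contrast_b %in% meta$karyotype)) {
    in_b <- meta$karyotype %in% cfg$contrast_b
    de_b <- stage("concord", nb_differential_test(
      counts_f[, in_b, drop = FALSE], meta$karyotype[in_b],
      contrast = cfg$contrast_b, config = dec))
    da <- call_degs(de_a, dec); db <- call_degs(de_b, dec)
    sh <- shared_degs(da$gene_id, db$gene_id)
    ia <- interaction_classification(
      sh, stats::setNames(da$log2_fold_change, da$gene_id),
      stats::setNames(db$log2_fold_change, db$gene_id))
    jsonlite::write_json(ia[setdiff(names(ia), "classes")],
                         file.path(out_dir, "interaction.json"), auto_unbox = TRUE)
    res$concordance <- ia
  }
  if ("ase" %in% cfg$stages) {
    kj <- karyotype_spec(1, 2)
    aseim <- stage("ase", simulate_allele_counts(kj, seed = cfg$seed))
    calls <- ase_calls(aseim$records)
    write_ase_calls(calls, file.path(out_dir, "ase_calls.tsv"))
    res$ase <- calls
  }
  if ("methylation" %in% cfg$stages) {
    blocks <- data.frame(start = c(20000, 60000), end = c(20500, 60500),
                         delta = 0.4)
    ms <- stage("methylation", simulate_methylation_dataset(
      planted_dmrs = blocks, seed = cfg$seed))
    ct <- cpg_differential_test(ms$cpgs, groups = c("case", "control"))
    dmrs <- call_dmrs(ct)
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    res$dmrs <- dmrs
  }

  resolved <- cfg[order(names(cfg))]
  cfgfile <- file.path(out_dir, "config_resolved.json")
  jsonlite::write_json(resolved, cfgfile, auto_unbox = TRUE, digits = NA)
  manifest <- list(r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("aneudose")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfgfile)),
                   stages = cfg$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
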