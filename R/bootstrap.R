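# clone-resampling bootstrap: DEG stability against clonal variation

#' Resample one clone per patient
#'
#' Uniformly selects exactly one sample (clone) from each patient's pool and
#' excludes that patient's other clones - the unit step of the stability
#' bootstrap.
#'
#' @param meta Sample metadata with `sample_id` and `patient`.
#' @return Character vector of selected sample ids (one per patient, in
#'   patient order of first appearance).
#' @export
resample_clones <- function(meta) {
  stopifnot(all(c("sample_id", "patient") %in% names(meta)))
  if (anyNA(meta$patient) || any(!nzchar(meta$patient)))
    stop("every sample needs a patient id")
  patients <- unique(meta$patient)
  vapply(patients, function(p) {
    pool <- meta$sample_id[meta$patient == p]
    if (!length(pool)) stop("patient with zero samples: ", p)
    pool[sample.int(length(pool), 1L)]
  }, character(1))
}

#' Bootstrap DEG stability over clone resamplings
#'
#' Runs `n_iter` iterations; in each, one clone is drawn per patient, size
#' factors are recomputed on the subset, the NB-Wald test is run for the
#' contrast, and DEGs are called at the study thresholds. Reports, per gene,
#' the percentage of iterations in which it was called a DEG. The gene set is
#' the (already filtered) input matrix throughout; no per-iteration
#' refiltering.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param meta Sample metadata with `sample_id`, `patient`, `karyotype`.
#' @param contrast Length-2 character `c(case, control)` of karyotype labels.
#' @param n_iter Number of bootstrap iterations (study default 50).
#' @param config A [de_config()].
#' @param seed Integer seed; fixed seed gives identical results.
#' @return data.frame sorted by gene_id: `gene_id`, `pct_iterations_deg`,
#'   `n_iterations`.
#' @export
bootstrap_deg_stability <- function(counts, meta, contrast, n_iter = 50L,
                                    config = de_config(), seed = 1L) {
  counts <- as.matrix(counts)
  stopifnot(all(meta$sample_id %in% colnames(counts)))
  meta <- meta[meta$karyotype %in% contrast, ]
  if (!all(contrast %in% meta$karyotype))
    stop("contrast group(s) absent from metadata: ",
         paste(setdiff(contrast, meta$karyotype), collapse = ", "))
  gid <- sort(rownames(counts))
  hits <- stats::setNames(numeric(length(gid)), gid)
  set.seed(substream_seed(seed, "bootstrap"))
  for (it in seq_len(n_iter)) {
    sel <- resample_clones(meta)
    sub <- meta[match(sel, meta$sample_id), ]
    if (!all(contrast %in% sub$karyotype))
      stop("a contrast group was emptied by resampling")
    cm <- counts[, sub$sample_id, drop = FALSE]
    res <- nb_differential_test(cm, sub$karyotype, contrast = contrast,
                                config = config)
    deg <- call_degs(res, config)
    hits[deg$gene_id] <- hits[deg$gene_id] + 1
  }
  data.frame(gene_id = gid, pct_iterations_deg = 100 * hits / n_iter,
             n_iterations = n_iter, row.names = NULL, stringsAsFactors = FALSE)
}
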