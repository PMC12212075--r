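# allele-specific expression: allelic fractions, mono/biallelic status,
# PAR-on-X reporting convention, territory-wise cluster summaries

#' Allelic fraction of a SNP record
#'
#' Reference-allele share `ref / (ref + alt)` and total depth. Depth 0 gives
#' an undefined (NA) fraction, classified LOW_COVERAGE downstream.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @return data.frame with `fraction` and `depth`.
#' @export
allelic_fraction <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0)) stop("negative allele counts")
  depth <- ref_count + alt_count
  data.frame(fraction = ifelse(depth > 0, ref_count / depth, NA_real_),
             depth = depth)
}

#' Classify a SNP as mono- or biallelically expressed
#'
#' BIALLELIC iff depth >= `min_depth` and the minor-allele share is at least
#' `minor_fraction_threshold`; MONOALLELIC when covered but below it;
#' LOW_COVERAGE otherwise. Defaults (10 reads, 10%) are declared conventions.
#'
#' @param fraction,depth As returned by [allelic_fraction()].
#' @param min_depth,minor_fraction_threshold Classification thresholds.
#' @return Character vector of statuses.
#' @export
classify_snp_expression <- function(fraction, depth, min_depth = 10,
                                    minor_fraction_threshold = 0.10) {
  status <- rep("LOW_COVERAGE", length(depth))
  cov <- depth >= min_depth & !is.na(fraction)
  minor <- pmin(fraction, 1 - fraction)
  # tolerance keeps the call symmetric under ref/alt swap (1 - (1 - f) != f
  # in floating point at the threshold)
  bi <- minor >= minor_fraction_threshold - 1e-9
  status[cov & bi] <- "BIALLELIC"
  status[cov & !bi] <- "MONOALLELIC"
  status
}

#' Apply the PAR-on-X reporting convention
#'
#' PAR SNPs (given in X or Y coordinates) are reported on chromosome X -
#' the convention of masking the Y PARs so every expressed PAR SNP maps to X.
#' NPY SNPs stay on Y and are flagged hemizygous.
#'
#' @param chrom,pos SNP coordinates (bp, 0-based).
#' @param tmap A [territory_map()].
#' @return data.frame `assigned_chrom`, `territory`, `hemizygous`.
#' @export
par_assignment <- function(chrom, pos, tmap = territory_map()) {
  terr <- classify_territory(chrom, pos, pos + 1, tmap)
  ch <- .norm_chrom(chrom)
  assigned <- ifelse(ch %in% c("X", "Y"), paste0("chr", ch), as.character(chrom))
  assigned[terr %in% c("PAR1", "PAR2")] <- "chrX"
  data.frame(assigned_chrom = assigned, territory = terr,
             hemizygous = terr == "NPY", stringsAsFactors = FALSE)
}

#' Build ASE calls from allele-count records
#'
#' Convenience wrapper: fraction, depth, status and PAR-convention chromosome
#' for a records table.
#'
#' @param records data.frame with `snp_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count` (and optionally `sample_id`, `gene_id`).
#' @param min_depth,minor_fraction_threshold See [classify_snp_expression()].
#' @param tmap A [territory_map()].
#' @return The records with `fraction`, `depth`, `status`, `assigned_chrom`,
#'   `territory`, `hemizygous` columns added.
#' @export
ase_calls <- function(records, min_depth = 10, minor_fraction_threshold = 0.10,
                      tmap = territory_map()) {
  af <- allelic_fraction(records$ref_count, records$alt_count)
  pa <- par_assignment(records$chrom, records$pos, tmap)
  records$fraction <- af$fraction
  records$depth <- af$depth
  records$status <- classify_snp_expression(af$fraction, af$depth, min_depth,
                                            minor_fraction_threshold)
  records$assigned_chrom <- pa$assigned_chrom
  if (is.null(records$territory)) records$territory <- pa$territory
  records$hemizygous <- pa$hemizygous
  records
}

# binomial mixture log-likelihood and EM for 2 components; deterministic
# initialization at (1/3, 2/3)
.binmix_loglik <- function(ref, depth, p, w) {
  comp <- vapply(seq_along(p), function(k)
    log(w[k]) + stats::dbinom(ref, depth, p[k], log = TRUE), numeric(length(ref)))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = length(ref))
  m <- apply(comp, 1, max)
  sum(m + log(rowSums(exp(comp - m))))
}

.binmix2_em <- function(ref, depth, init = c(1/3, 2/3), max_iter = 200, tol = 1e-8) {
  p <- init; w <- c(0.5, 0.5); ll_old <- -Inf
  eps <- 1e-6
  for (it in seq_len(max_iter)) {
    l1 <- log(w[1]) + stats::dbinom(ref, depth, p[1], log = TRUE)
    l2 <- log(w[2]) + stats::dbinom(ref, depth, p[2], log = TRUE)
    m <- pmax(l1, l2)
    r1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    w <- c(mean(r1), 1 - mean(r1))
    p[1] <- min(max(sum(r1 * ref) / sum(r1 * depth), eps), 1 - eps)
    p[2] <- min(max(sum((1 - r1) * ref) / sum((1 - r1) * depth), eps), 1 - eps)
    ll <- .binmix_loglik(ref, depth, p, w)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(p = p, w = w, loglik = ll_old, resp1 = r1)
}

#' Summarize allelic-fraction clusters of a SNP group
#'
#' Decides between one and two allelic clusters by BIC of 1- vs 2-component
#' binomial mixtures on (ref, depth), with deterministic initialization at
#' (1/3, 2/3). A unimodal group returns the mean fraction as its single
#' center; a bimodal one returns the two component-wise mean fractions.
#'
#' @param ref_count,depth Per-SNP reference counts and depths (biallelic
#'   calls of one territory x karyotype group).
#' @param min_calls Minimum calls required for mode estimation (default 20).
#' @return List: `n_modes` (0 when insufficient), `centers` (fractions),
#'   `dispersion` (sd of fractions about the nearest center), `bic`
#'   (both models), `insufficient` flag.
#' @export
cluster_summary <- function(ref_count, depth, min_calls = 20L) {
  ok <- depth > 0 & !is.na(ref_count)
  ref <- ref_count[ok]; dep <- depth[ok]
  n <- length(ref)
  if (n < min_calls)
    return(list(n_modes = 0L, centers = numeric(0), dispersion = NA_real_,
                bic = c(one = NA_real_, two = NA_real_), insufficient = TRUE))
  frac <- ref / dep
  p1 <- sum(ref) / sum(dep)
  ll1 <- sum(stats::dbinom(ref, dep, min(max(p1, 1e-6), 1 - 1e-6), log = TRUE))
  bic1 <- -2 * ll1 + 1 * log(n)
  em <- .binmix2_em(ref, dep)
  ll2 <- .binmix_loglik(ref, dep, em$p, em$w)
  bic2 <- -2 * ll2 + 3 * log(n)
  if (bic1 <= bic2) {
    centers <- mean(frac)
    disp <- stats::sd(frac)
    k <- 1L
  } else {
    assign1 <- em$resp1 >= 0.5
    centers <- sort(c(
      if (any(assign1)) mean(frac[assign1]) else em$p[1],
      if (any(!assign1)) mean(frac[!assign1]) else em$p[2]))
    disp <- stats::sd(frac - centers[1 + (frac > mean(centers))])
    k <- 2L
  }
  list(n_modes = k, centers = centers, dispersion = disp,
       bic = c(one = bic1, two = bic2), insufficient = FALSE)
}

#' Read/write allele-count and ASE tables
#'
#' VCF-like TSV with columns CHROM, POS, SNP_ID, GENE_ID, SAMPLE, REF_COUNT,
#' ALT_COUNT (header required, case-insensitive).
#'
#' @param path File path.
#' @return Records data.frame with package-internal column names.
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv(path)
  names(df) <- tolower(names(df))
  map <- c(chrom = "chrom", pos = "pos", snp_id = "snp_id", gene_id = "gene_id",
           sample = "sample_id", sample_id = "sample_id",
           ref_count = "ref_count", alt_count = "alt_count")
  names(df) <- ifelse(names(df) %in% names(map), map[names(df)], names(df))
  need <- c("chrom", "pos", "snp_id", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele-count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_allele_counts
#' @param calls ASE call table ([ase_calls()] output).
#' @export
write_ase_calls <- function(calls, path) write_tsv(calls, path)
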