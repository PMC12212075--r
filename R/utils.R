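# shared helpers: deterministic seed sub-streams and small IO wrappers

#' Derive a deterministic sub-stream seed
#'
#' Mixes a global seed with a stage name so every generator draws from its own
#' reproducible stream: adding a generator never perturbs the draws of another.
#' The result is always in [1, 2^31 - 2].
#'
#' @param seed Integer global seed.
#' @param name Character stage label.
#' @return Integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; doubles stay exact below 2^53
  h <- 0
  for (c in utf8ToInt(as.character(name))) h <- (h * 131 + c) %% m
  as.integer((((h + 1) * 69069) %% m + (abs(seed) %% m)) %% (m - 1) + 1)
}

#' Write a matrix as TSV with an id column
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_name Header of the id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path File path.
#' @return Numeric matrix with the first column as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write/read a plain data.frame TSV
#' @param df Data frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Benjamini-Hochberg with NA passthrough; thin wrapper kept in one place so
# every module adjusts identically.
.bh <- function(p) stats::p.adjust(p, method = "BH")
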