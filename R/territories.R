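#' Sex-chromosome territory map
#'
#' Coordinates of the two pseudoautosomal regions on X and Y. Defaults are the
#' GRCh38 PAR boundaries (X PAR1 10,001-2,781,479; X PAR2 155,701,383-156,030,895,
#' 1-based inclusive; the Y intervals mirror them at the Yp/Yq tips). All
#' intervals are stored 0-based half-open, the package-internal convention.
#'
#' @param par1_x,par1_y,par2_x,par2_y Length-2 numeric vectors, 0-based
#'   half-open `[start, end)` in base pairs.
#' @param assembly_label Free-text label of the assembly the map refers to.
#' @return An object of class `territory_map`.
#' @export
territory_map <- function(par1_x = c(10000L, 2781479L),
                          par1_y = c(10000L, 2781479L),
                          par2_x = c(155701382L, 156030895L),
                          par2_y = c(56887902L, 57217415L),
                          assembly_label = "GRCh38") {
  tm <- list(par1_x = as.numeric(par1_x), par1_y = as.numeric(par1_y),
             par2_x = as.numeric(par2_x), par2_y = as.numeric(par2_y),
             assembly_label = assembly_label)
  for (nm in c("par1_x", "par1_y", "par2_x", "par2_y")) {
    iv <- tm[[nm]]
    if (length(iv) != 2L || !all(is.finite(iv)) || iv[1] >= iv[2])
      stop("territory_map: interval '", nm, "' must be a non-empty [start, end)")
  }
  if (tm$par1_x[2] > tm$par2_x[1])
    stop("territory_map: PAR1 must precede PAR2 on X and the intervals must not overlap")
  if (tm$par1_y[2] > tm$par2_y[1])
    stop("territory_map: PAR1 and PAR2 on Y must not overlap")
  class(tm) <- "territory_map"
  tm
}

#' @export
print.territory_map <- function(x, ...) {
  cat("territory_map (", x$assembly_label, ")\n", sep = "")
  cat(sprintf("  PAR1 X [%d, %d)  Y [%d, %d)\n", x$par1_x[1], x$par1_x[2],
              x$par1_y[1], x$par1_y[2]))
  cat(sprintf("  PAR2 X [%d, %d)  Y [%d, %d)\n", x$par2_x[1], x$par2_x[2],
              x$par2_y[1], x$par2_y[2]))
  invisible(x)
}

TERRITORY_LEVELS <- c("AUTOSOME", "PAR1", "PAR2", "NPX", "NPY", "MT")

.norm_chrom <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  ch[ch %in% c("M", "MT")] <- "MT"
  accepted <- c(as.character(1:22), "X", "Y", "MT")
  bad <- setdiff(unique(ch), accepted)
  if (length(bad))
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "),
         "; accepted: chr1-chr22, chrX, chrY, chrM (with or without 'chr' prefix)")
  ch
}

#' Classify a genomic interval into a sex-chromosome territory
#'
#' PAR membership is decided by the interval midpoint (genes straddling a PAR
#' boundary are rare and documented as midpoint-classified). X outside the PARs
#' is NPX, Y outside is NPY, the mitochondrial chromosome is MT, everything
#' else AUTOSOME.
#'
#' @param chrom Chromosome name (`chr1`..`chr22`, `chrX`, `chrY`, `chrM`;
#'   the `chr` prefix is optional).
#' @param start,end 0-based half-open interval in bp.
#' @param tmap A [territory_map()].
#' @return One of `"AUTOSOME"`, `"PAR1"`, `"PAR2"`, `"NPX"`, `"NPY"`, `"MT"`.
#'   Vectorised over `chrom`, `start`, `end`.
#' @export
classify_territory <- function(chrom, start, end, tmap = territory_map()) {
  stopifnot(inherits(tmap, "territory_map"))
  if (any(!is.finite(start) | !is.finite(end) | start >= end))
    stop("classify_territory: need valid intervals with start < end")
  ch <- .norm_chrom(chrom)
  mid <- (as.numeric(start) + as.numeric(end)) / 2
  res <- rep("AUTOSOME", length(ch))
  res[ch == "MT"] <- "MT"
  inx <- function(iv) mid >= iv[1] & mid < iv[2]
  isx <- ch == "X"
  isy <- ch == "Y"
  res[isx] <- "NPX"
  res[isy] <- "NPY"
  res[isx & inx(tmap$par1_x)] <- "PAR1"
  res[isx & inx(tmap$par2_x)] <- "PAR2"
  res[isy & inx(tmap$par1_y)] <- "PAR1"
  res[isy & inx(tmap$par2_y)] <- "PAR2"
  res
}

#' Assign territories to a gene table
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`, `homolog_id`.
#' @param tmap A [territory_map()].
#' @return The input with a `territory` column (and `length = end - start`).
#' @export
assign_gene_territories <- function(genes, tmap = territory_map()) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(genes) == 0L) {
    genes$territory <- character(0)
    genes$length <- numeric(0)
    return(genes)
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  genes$territory <- classify_territory(genes$chrom, genes$start, genes$end, tmap)
  genes$length <- as.numeric(genes$end) - as.numeric(genes$start)
  if (is.null(genes$strand)) genes$strand <- "."
  if (is.null(genes$homolog_id)) genes$homolog_id <- NA_character_
  genes
}

#' Bundled GRCh38 pseudoautosomal gene annotation
#'
#' The 25 PAR1 and 4 PAR2 genes of the Ensembl-style GRCh38 annotation, as
#' X-chromosome records (the bioinformatic convention reports PAR genes on X
#' with the Y copy masked). Coordinates are approximate gene spans inside the
#' PAR intervals; XG straddles the PAR1 boundary and is bundled with its end
#' trimmed to the boundary so the midpoint rule keeps it in PAR1.
#'
#' @return A GeneRecord data.frame with territories assigned.
#' @export
par_gene_annotation <- function() {
  p1 <- c("PLCXD1",    276321,  303356, "+",
          "LINC00685", 281054,  292512, "-",
          "GTPBP6",    304528,  318819, "-",
          "PPP2R3B",   333932,  386907, "-",
          "SHOX",      624343,  659411, "-",
          "CRLF2",    1190448, 1212815, "-",
          "CSF2RA",   1268799, 1309935, "+",
          "IL3RA",    1336607, 1382689, "+",
          "SLC25A6",  1386151, 1392113, "-",
          "ASMTL-AS1",1403139, 1421097, "-",
          "ASMTL",    1422197, 1453795, "+",
          "P2RY8",    1462570, 1537185, "-",
          "AKAP17A",  1591603, 1602520, "+",
          "ASMT",     1615058, 1643081, "+",
          "DPH3P2",   1717556, 1718568, "-",
          "MIR6089",  1737025, 1737110, "+",
          "DHRSX",    2137559, 2419008, "+",
          "LINC00102",2236256, 2245869, "+",
          "LINC00106",2268619, 2288644, "-",
          "LINC00107",2319969, 2345652, "+",
          "ZBED1",    2486434, 2500976, "+",
          "CD99P1",   2541527, 2563466, "-",
          "MIR3690",  2609190, 2609268, "+",
          "CD99",     2691186, 2741309, "+",
          "XG",       2751707, 2781479, "+")
  p2 <- c("SPRY3",  155712367, 155782459, "+",
          "VAMP7",  155880573, 155943769, "+",
          "IL9R",   155997580, 156013016, "+",
          "WASH6P", 156016837, 156030557, "+")
  m <- matrix(c(p1, p2), ncol = 4, byrow = TRUE)
  genes <- data.frame(gene_id = m[, 1],
                      chrom = "chrX",
                      start = as.numeric(m[, 2]),
                      end = as.numeric(m[, 3]),
                      strand = m[, 4],
                      stringsAsFactors = FALSE)
  assign_gene_territories(genes)
}

#' Bundled NPX-NPY homolog pair table
#'
#' X-Y gene pairs from the diverged non-pseudoautosomal regions, covering the
#' pairs examined in sex-aneuploid expression contrasts (e.g. UTY-KDM6A,
#' DDX3Y-DDX3X). Y pseudogenes without a functional partner (e.g. TTTY14) are
#' intentionally absent: lookups return `NA` rather than a guessed partner.
#'
#' @return data.frame with columns `npx_gene`, `npy_gene`.
#' @export
homolog_pair_table <- function() {
  tab <- data.frame(
    npx_gene = c("NLGN4X", "EIF1AX", "DDX3X", "TXLNG", "ZFX", "KDM6A",
                 "USP9X", "KDM5C", "ANOS1", "BCOR", "RPS4X", "TMSB4X",
                 "AMELX", "PRKX", "TBL1X", "TSPYL2"),
    npy_gene = c("NLGN4Y", "EIF1AY", "DDX3Y", "TXLNGY", "ZFY", "UTY",
                 "USP9Y", "KDM5D", "ANOS2P", "BCORP1", "RPS4Y1", "TMSB4Y",
                 "AMELY", "PRKY", "TBL1Y", "TSPY1"),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(c(tab$npx_gene, tab$npy_gene)))
  tab
}

#' Look up the X-Y homolog partner of a gene
#'
#' Symmetric: works from either side of the pair.
#'
#' @param gene_id Gene symbol.
#' @param table A homolog pair table, by default [homolog_pair_table()].
#' @return Partner gene symbol, or `NA_character_` when the gene has no
#'   annotated partner.
#' @export
homolog_lookup <- function(gene_id, table = homolog_pair_table()) {
  stopifnot(is.data.frame(table), all(c("npx_gene", "npy_gene") %in% names(table)))
  out <- rep(NA_character_, length(gene_id))
  ix <- match(gene_id, table$npx_gene)
  out[!is.na(ix)] <- table$npy_gene[ix[!is.na(ix)]]
  iy <- match(gene_id, table$npy_gene)
  out[!is.na(iy)] <- table$npx_gene[iy[!is.na(iy)]]
  out
}

#' Read a BED6+ gene annotation
#'
#' Columns: chrom, start, end, gene_id, score, strand, and optionally a 7th
#' `territory` column. BED is natively 0-based half-open, the internal
#' convention, so coordinates are taken as-is.
#'
#' @param path File path.
#' @param tmap Territory map used when the file carries no territory column.
#' @return GeneRecord data.frame.
#' @export
read_bed_annotation <- function(path, tmap = territory_map()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L) stop("BED6+ requires at least 6 columns: ", path)
  genes <- data.frame(gene_id = as.character(df[[4]]), chrom = df[[1]],
                      start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                      strand = as.character(df[[6]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 7L) {
    genes$territory <- as.character(df[[7]])
    bad <- setdiff(unique(genes$territory), TERRITORY_LEVELS)
    if (length(bad)) stop("unknown territory label(s): ", paste(bad, collapse = ", "))
    genes$length <- genes$end - genes$start
    genes$homolog_id <- NA_character_
    genes
  } else {
    assign_gene_territories(genes, tmap)
  }
}

#' Write a gene annotation as BED6+territory
#' @param genes GeneRecord data.frame with territories.
#' @param path Output path.
#' @export
write_bed_annotation <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "territory") %in% names(genes)))
  strand <- if (is.null(genes$strand)) "." else genes$strand
  out <- data.frame(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$gene_id, 0L, strand, genes$territory)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal GTF subset (gene lines only)
#'
#' Parses only `gene` feature rows and the `gene_id` attribute. GTF is 1-based
#' inclusive; coordinates are converted to the internal 0-based half-open
#' convention on read.
#'
#' @param path File path.
#' @param tmap Territory map for classification.
#' @return GeneRecord data.frame.
#' @export
read_gtf_lite <- function(path, tmap = territory_map()) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))
  f <- f[keep]
  if (!length(f)) stop("no gene feature lines in ", path)
  gid <- vapply(f, function(x) {
    m <- regmatches(x[9], regexpr('gene_id "[^"]+"', x[9]))
    if (!length(m)) stop("GTF gene line without gene_id attribute")
    sub('gene_id "([^"]+)"', "\\1", m)
  }, character(1))
  genes <- data.frame(gene_id = gid,
                      chrom = vapply(f, `[`, character(1), 1),
                      start = vapply(f, function(x) as.numeric(x[4]), numeric(1)) - 1,
                      end = vapply(f, function(x) as.numeric(x[5]), numeric(1)),
                      strand = vapply(f, `[`, character(1), 7),
                      stringsAsFactors = FALSE)
  assign_gene_territories(genes, tmap)
}
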