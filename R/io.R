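#' Read a cellranger-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (feature ids, one per row of the
#' matrix) and `barcodes.tsv` (cell ids, one per column).
#'
#' @param dir Directory containing the three files.
#' @return A features x cells `dgCMatrix` with dimnames attached.
#' @export
read_mtx_triplet <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc)) {
    if (!file.exists(f)) stop("format error: missing file ", f)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readLines(feat)
  barcodes <- readLines(bc)
  if (nrow(m) != length(features)) {
    stop("format error: matrix has ", nrow(m), " rows but features.tsv has ",
         length(features), " entries")
  }
  if (ncol(m) != length(barcodes)) {
    stop("format error: matrix has ", ncol(m), " columns but barcodes.tsv has ",
         length(barcodes), " entries")
  }
  if (any(m@x < 0)) stop("format error: negative counts in matrix")
  dimnames(m) <- list(features, barcodes)
  m
}

#' Write a sparse matrix as a Matrix Market triplet directory
#'
#' @param m A features x cells sparse matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the files written.
#' @export
write_mtx_triplet <- function(m, dir) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), mtx)
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv")))
}

#' Read a BED file of genomic intervals
#'
#' Minimal validating reader for BED3(+name). Intervals are 0-based
#' half-open on disk and returned as a `GRanges` (1-based closed, the R
#' convention); the conversion happens only here. `track`, `browser` and
#' `#` comment lines are skipped. Malformed lines are rejected with their
#' line numbers.
#'
#' @param path BED file path.
#' @return A `GRanges`, with names from column 4 when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("format error: fewer than 3 tab-separated columns on line ",
         paste(idx[nf < 3], collapse = ", "))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("format error: non-numeric coordinates on line ",
         paste(idx[bad], collapse = ", "))
  }
  bad <- start >= end | start < 0
  if (any(bad)) {
    stop("format error: start >= end (or start < 0) on line ",
         paste(idx[bad], collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  has4 <- nf >= 4
  if (all(has4)) names(gr) <- vapply(fields, `[`, "", 4L)
  gr
}

#' Write a `GRanges` as BED (0-based half-open)
#'
#' @param gr A `GRanges`; names become column 4 when present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(names(gr))) df$name <- names(gr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated with at least `variant_id`, `chrom`, `pos` (1-based, VCF
#' convention), `ref`, `alt`; optional `type`, `branch`, `wgs_baf`.
#'
#' @param path TSV path.
#' @return A data frame of variant records.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: variant table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) && any(df$pos < 1)) {
    stop("format error: variant positions must be 1-based (>= 1)")
  }
  if ("wgs_baf" %in% names(df)) {
    ok <- is.na(df$wgs_baf) | (df$wgs_baf >= 0 & df$wgs_baf <= 1)
    if (!all(ok)) stop("format error: wgs_baf outside [0,1]")
  }
  df
}

#' Read a per-cell allele-count table
#'
#' Long format as produced by single-cell read counters: one row per
#' (cell, variant) with REF and ALT read counts. Duplicate (cell, variant)
#' rows are summed with a warning.
#'
#' @param path TSV path with columns `cell_id`, `variant_id`, `ref_reads`,
#'   `alt_reads`.
#' @return A data frame with one row per (cell, variant).
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "variant_id", "ref_reads", "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: allele-count table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  if (any(df$ref_reads < 0 | df$alt_reads < 0)) {
    stop("format error: negative read counts")
  }
  key <- paste(df$cell_id, df$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (cell, variant) rows summed")
    agg <- stats::aggregate(df[c("ref_reads", "alt_reads")],
                            by = list(key = key), FUN = sum)
    first <- df[!duplicated(key), c("cell_id", "variant_id")]
    first <- first[match(agg$key, key[!duplicated(key)]), ]
    df <- data.frame(first, agg[c("ref_reads", "alt_reads")],
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  df
}
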