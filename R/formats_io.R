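#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased on read; the fraction of soft-masked (lowercase)
#' bases in the original record is preserved in `mcols(x)$masked_fraction`
#' so that downstream consumers do not silently lose RepeatMasker-style
#' masking information. Only the alphabet `A,C,G,T,N` is accepted after
#' uppercasing. Reading is gzip-transparent.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet] with per-record metadata column
#'   `masked_fraction`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgT"), tf)
#' x <- read_fasta(tf)
#' as.character(x)                      # "ACGT"
#' S4Vectors::mcols(x)$masked_fraction  # 0.75
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA parse error: no records in '", path, "'")
  if (any(Biostrings::width(raw) == 0L))
    stop("FASTA parse error: empty sequence for record '",
         names(raw)[which(Biostrings::width(raw) == 0L)[1L]], "'")
  n_lower <- Biostrings::letterFrequency(raw, letters = "acgtn")
  masked_fraction <- as.numeric(n_lower) / Biostrings::width(raw)
  up <- Biostrings::BStringSet(toupper(as.character(raw)))
  bad <- Biostrings::letterFrequency(up, letters = "ACGTN")
  if (any(as.numeric(bad) != Biostrings::width(up))) {
    i <- which(as.numeric(bad) != Biostrings::width(up))[1L]
    stop("FASTA parse error: record '", names(raw)[i],
         "' contains characters outside {A,C,G,T,N}")
  }
  out <- Biostrings::DNAStringSet(up)
  names(out) <- names(raw)
  S4Vectors::mcols(out)$masked_fraction <- masked_fraction
  out
}

#' Write DNA sequences to FASTA (60-column wrapping)
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.strand_ok <- c("+", "-", ".")

.validate_intervals <- function(chrom, start, end, strand, lines, path) {
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad))
    stop("interval validation error in '", path, "' line ", lines[bad[1L]],
         ": require 0 <= start < end, got start=", start[bad[1L]],
         " end=", end[bad[1L]])
  bad <- which(!(strand %in% .strand_ok))
  if (length(bad))
    stop("interval validation error in '", path, "' line ", lines[bad[1L]],
         ": unknown strand symbol '", strand[bad[1L]], "'")
  invisible(TRUE)
}

#' Read BED-family interval files
#'
#' Supports three dialects used throughout the pipeline, all 0-based
#' half-open:
#' * `"bed6"`: chrom, start, end, name, score, strand (3 columns minimum).
#' * `"narrowPeak"`: ENCODE 10-column format; column 7 becomes `signal`,
#'   column 9 `q_value` (-log10 scale), column 10 `summit_offset` (the
#'   sentinel `-1` becomes `NA`).
#' * `"repeat_table"`: RepeatMasker-derived table with header columns
#'   `chrom, start, end, strand, family, superfamily` (plus optional `name`).
#'
#' @param path Path to a tab-separated file (gzip-transparent).
#' @param kind One of `"bed6"`, `"narrowPeak"`, `"repeat_table"`.
#' @return A [GenomicRanges::GRanges]; metadata columns depend on `kind`.
#' @export
read_bed <- function(path, kind = c("bed6", "narrowPeak", "repeat_table")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  header <- kind == "repeat_table"
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  lines <- seq_len(nrow(df)) + as.integer(header)
  if (kind == "bed6") {
    if (ncol(df) < 3L) stop("bed6 requires >= 3 columns in '", path, "'")
    chrom <- as.character(df[[1L]])
    start <- as.integer(df[[2L]]); end <- as.integer(df[[3L]])
    name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else rep(".", nrow(df))
    score <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else rep(0, nrow(df))
    strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else rep(".", nrow(df))
    .validate_intervals(chrom, start, end, strand, lines, path)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                                 strand = sub("^\\.$", "*", strand))
    S4Vectors::mcols(gr)$name <- name
    S4Vectors::mcols(gr)$score <- score
  } else if (kind == "narrowPeak") {
    if (ncol(df) < 10L) stop("narrowPeak requires 10 columns in '", path, "'")
    chrom <- as.character(df[[1L]])
    start <- as.integer(df[[2L]]); end <- as.integer(df[[3L]])
    strand <- as.character(df[[6L]])
    .validate_intervals(chrom, start, end, strand, lines, path)
    signal <- as.numeric(df[[7L]])
    if (any(!is.finite(signal)))
      stop("narrowPeak validation error in '", path, "': non-finite signal")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                                 strand = sub("^\\.$", "*", strand))
    S4Vectors::mcols(gr)$name <- as.character(df[[4L]])
    S4Vectors::mcols(gr)$signal <- signal
    S4Vectors::mcols(gr)$p_value <- as.numeric(df[[8L]])
    qv <- as.numeric(df[[9L]])
    qv[qv < 0] <- NA_real_
    S4Vectors::mcols(gr)$q_value <- qv
    so <- as.integer(df[[10L]])
    so[so < 0L] <- NA_integer_
    S4Vectors::mcols(gr)$summit_offset <- so
  } else {
    need <- c("chrom", "start", "end", "strand", "family", "superfamily")
    if (!all(need %in% names(df)))
      stop("repeat_table in '", path, "' must have columns: ",
           paste(need, collapse = ", "))
    chrom <- as.character(df$chrom)
    start <- as.integer(df$start); end <- as.integer(df$end)
    strand <- as.character(df$strand)
    .validate_intervals(chrom, start, end, strand, lines, path)
    if (any(!nzchar(df$family)))
      stop("repeat_table validation error in '", path, "': empty family")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                                 strand = sub("^\\.$", "*", strand))
    S4Vectors::mcols(gr)$name <-
      if ("name" %in% names(df)) as.character(df$name)
      else paste0(df$family, "_", seq_len(nrow(df)))
    S4Vectors::mcols(gr)$family <- as.character(df$family)
    S4Vectors::mcols(gr)$superfamily <- as.character(df$superfamily)
  }
  gr
}

#' Write intervals in a BED-family dialect
#'
#' Inverse of [read_bed()]; coordinates are emitted 0-based half-open.
#'
#' @param gr A [GenomicRanges::GRanges] with the metadata columns that
#'   [read_bed()] produces for the chosen `kind`.
#' @param path Output path.
#' @param kind One of `"bed6"`, `"narrowPeak"`, `"repeat_table"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, kind = c("bed6", "narrowPeak", "repeat_table")) {
  kind <- match.arg(kind)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  strand <- sub("^\\*$", ".", as.character(GenomicRanges::strand(gr)))
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) mc$name else rep(".", length(gr))
  if (kind == "bed6") {
    score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
    df <- data.frame(chrom, start, end, nm, score, strand)
  } else if (kind == "narrowPeak") {
    qv <- mc$q_value
    qv[is.na(qv)] <- -1
    so <- mc$summit_offset
    so[is.na(so)] <- -1L
    df <- data.frame(chrom, start, end, nm, 0L, strand,
                     mc$signal, mc$p_value, qv, so)
  } else {
    df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                     family = mc$family, superfamily = mc$superfamily,
                     name = nm)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = kind == "repeat_table")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Steps are sorted per chromosome and validated to be non-overlapping
#' (tracks must be flat, as produced by genome-wide coverage callers).
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A [GenomicRanges::GRanges] with numeric `score`, sorted.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("bedGraph requires 4 columns in '", path, "'")
  value <- suppressWarnings(as.numeric(df[[4L]]))
  if (any(!is.finite(value)))
    stop("bedGraph validation error in '", path, "' line ",
         which(!is.finite(value))[1L], ": non-numeric or non-finite value")
  chrom <- as.character(df[[1L]])
  start <- as.integer(df[[2L]]); end <- as.integer(df[[3L]])
  .validate_intervals(chrom, start, end, rep(".", nrow(df)),
                      seq_len(nrow(df)), path)
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]; value <- value[o]
  same <- chrom[-1L] == chrom[-length(chrom)]
  if (length(same) && any(same & start[-1L] < end[-length(end)]))
    stop("bedGraph validation error in '", path, "': overlapping steps")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$score <- value
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param gr A [GenomicRanges::GRanges] with a numeric `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   S4Vectors::mcols(gr)$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct an expression set (matrix + sample metadata)
#'
#' The container used throughout the pipeline for log2(TPM+1) expression of
#' genes and ERV loci. Feature identifiers must be unique and every matrix
#' column must have a metadata row with `condition` in \{control, PE\} and a
#' `batch` label.
#'
#' @param mat Numeric matrix, features x samples, with rownames and colnames.
#' @param meta Data frame with columns `sample`, `condition`, `batch`.
#' @return An object of class `expr_set` (list with `mat` and `meta`).
#' @export
expr_set <- function(mat, meta) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate feature id: '",
         rownames(mat)[duplicated(rownames(mat))][1L], "'")
  if (any(!is.finite(mat))) stop("expression values must be finite")
  need <- c("sample", "condition", "batch")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(mat), meta$sample)
  if (length(missing))
    stop("sample '", missing[1L], "' in matrix is missing from metadata")
  if (!all(meta$condition %in% c("control", "PE")))
    stop("condition must be 'control' or 'PE'")
  meta <- meta[match(colnames(mat), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(mat = mat, meta = meta), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set: ", nrow(x$mat), " features x ", ncol(x$mat), " samples (",
      sum(x$meta$condition == "PE"), " PE / ",
      sum(x$meta$condition == "control"), " control; ",
      length(unique(x$meta$batch)), " batch(es))\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' @param path TSV with a header row of sample ids; first column feature ids.
#' @param metadata_path TSV with columns `sample`, `condition`, `batch`.
#' @return An [expr_set()].
#' @export
read_expression <- function(path, metadata_path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id: '", ids[duplicated(ids)][1L],
         "' in '", path, "'")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expr_set(mat, meta)
}

#' Write an expression set to TSV files
#'
#' @param x An [expr_set()].
#' @param path Output TSV for the matrix (features x samples).
#' @param metadata_path Optional output TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  df <- data.frame(feature = rownames(x$mat), x$mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  if (!is.null(metadata_path))
    write.table(x$meta, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  invisible(path)
}
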