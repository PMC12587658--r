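#' Read a JASPAR plain-text count matrix
#'
#' Accepts the JASPAR 4-row format, with or without the `>` header line and
#' with or without the `A [ ... ]` row decorations.
#'
#' @param path Path to the count file.
#' @return A 4 x L numeric matrix with rownames `A,C,G,T`.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4L)
    stop("JASPAR matrix in '", path, "' must have 4 count rows")
  parse_row <- function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[?", "", l)
    l <- gsub("\\]", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  }
  rows <- lapply(lines, parse_row)
  if (length(unique(lengths(rows))) != 1L)
    stop("JASPAR matrix rows have unequal lengths")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  counts
}

#' Normalize a PWM count matrix to position-specific probabilities
#'
#' A pseudocount is added to every count before column-wise normalization, so
#' that no probability is exactly zero:
#' `p[b,i] = (count[b,i] + pc) / (sum_b count[b,i] + 4 * pc)`.
#'
#' @param counts 4 x L non-negative matrix, rows `A,C,G,T`.
#' @param pseudocount Value added to each count (default 1).
#' @return 4 x L probability matrix; each column sums to 1.
#' @export
normalize_pwm <- function(counts, pseudocount = 1) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  adj <- counts + pseudocount
  tot <- colSums(adj)
  if (any(tot <= 0))
    stop("PWM column with non-positive total after pseudocount")
  probs <- sweep(adj, 2L, tot, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  probs
}

.base_index <- function(kmer) {
  idx <- match(strsplit(kmer, "")[[1L]], c("A", "C", "G", "T"))
  idx  # NA for N
}

#' Score one k-mer against a probability PWM
#'
#' The raw score is the sum of log-transformed position probabilities,
#' `sum_i log(p[base_i, i] + epsilon)`. An `N` at position i contributes the
#' uniform probability, `log(0.25 + epsilon)`.
#'
#' @param pwm 4 x L probability matrix from [normalize_pwm()].
#' @param kmer Character string of length L over `A,C,G,T,N`.
#' @param epsilon Small offset inside the log (default 1e-6).
#' @return The raw log score (a single negative number for probability PWMs).
#' @export
score_window <- function(pwm, kmer, epsilon = 1e-6) {
  L <- ncol(pwm)
  if (nchar(kmer) != L)
    stop("k-mer length ", nchar(kmer), " does not match PWM length ", L)
  idx <- .base_index(kmer)
  p <- pwm[cbind(idx, seq_len(L))]
  p[is.na(idx)] <- 0.25
  sum(log(p + epsilon))
}

#' Attainable raw score range of a PWM
#'
#' @param pwm 4 x L probability matrix.
#' @param epsilon Log offset, as in [score_window()].
#' @return Named numeric vector `c(min = ..., max = ...)`, the column-wise
#'   sums of the smallest and largest log probabilities.
#' @export
pwm_score_range <- function(pwm, epsilon = 1e-6) {
  lp <- log(pwm + epsilon)
  c(min = sum(apply(lp, 2L, min)), max = sum(apply(lp, 2L, max)))
}

#' Min-max normalize a raw PWM score to [0, 1]
#'
#' The consensus k-mer (column-wise argmax) maps to 1 and the anti-consensus
#' to 0. A degenerate uniform PWM (zero range) returns 1 with a warning.
#'
#' @param raw Raw score(s) from [score_window()].
#' @param pwm 4 x L probability matrix.
#' @param epsilon Log offset, as in [score_window()].
#' @return Normalized score(s) in `[0, 1]`.
#' @export
normalize_score <- function(raw, pwm, epsilon = 1e-6) {
  rg <- pwm_score_range(pwm, epsilon)
  if (rg["max"] - rg["min"] <= 0) {
    warning("uniform PWM: score range is zero; normalized score set to 1")
    return(rep(1, length(raw)))
  }
  unname((raw - rg["min"]) / (rg["max"] - rg["min"]))
}

#' Scan a sequence with a PWM using a sliding window
#'
#' Every window of width `ncol(pwm)` at stride 1 is scored on the forward
#' strand (optionally also the reverse complement). All windows are reported;
#' the `passes` flag marks windows at or above the threshold of the chosen
#' mode: `raw_score >= raw_threshold` in raw mode, or
#' `normalized_score >= normalized_threshold` in normalized mode.
#'
#' @param sequence Character string (or length-1 `DNAStringSet`) over
#'   `A,C,G,T,N`.
#' @param pwm 4 x L probability matrix from [normalize_pwm()].
#' @param mode `"normalized"` (default) or `"raw"`.
#' @param raw_threshold Threshold on the raw log score (raw mode).
#' @param normalized_threshold Threshold on the min-max score (normalized
#'   mode), default 0.5.
#' @param epsilon Log offset, see [score_window()].
#' @param drop_n_windows If `TRUE`, windows containing `N` are dropped
#'   instead of scored at uniform probability.
#' @param both_strands If `TRUE`, the reverse complement is also scanned and
#'   a `strand` column is reported.
#' @return A data frame with columns `start` (0-based window start), `kmer`,
#'   `raw_score`, `normalized_score`, `passes` (and `strand` if both strands
#'   were scanned). Sequences shorter than the window yield zero rows.
#' @export
scan_sequence <- function(sequence, pwm,
                          mode = c("normalized", "raw"),
                          raw_threshold = 8,
                          normalized_threshold = 0.5,
                          epsilon = 1e-6,
                          drop_n_windows = FALSE,
                          both_strands = FALSE) {
  mode <- match.arg(mode)
  if (!is.character(sequence)) sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- ncol(pwm)
  scan_one <- function(seqchar, strand_label) {
    n <- nchar(seqchar)
    if (n < L)
      return(data.frame(start = integer(0), kmer = character(0),
                        raw_score = numeric(0), normalized_score = numeric(0),
                        passes = logical(0), strand = character(0)))
    chars <- strsplit(seqchar, "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T"))
    lp <- log(pwm + epsilon)
    lpn <- log(0.25 + epsilon)
    # per-position log-prob for each PWM column, NA-safe
    starts <- seq_len(n - L + 1L)
    raw <- numeric(length(starts))
    has_n <- logical(length(starts))
    for (j in seq_len(L)) {
      bi <- idx[starts + j - 1L]
      contrib <- lp[cbind(bi, rep(j, length(starts)))]
      nas <- is.na(bi)
      contrib[nas] <- lpn
      has_n <- has_n | nas
      raw <- raw + contrib
    }
    kmers <- substring(seqchar, starts, starts + L - 1L)
    df <- data.frame(start = starts - 1L, kmer = kmers, raw_score = raw,
                     normalized_score = normalize_score(raw, pwm, epsilon),
                     strand = strand_label, stringsAsFactors = FALSE)
    if (drop_n_windows) df <- df[!has_n, , drop = FALSE]
    df
  }
  out <- scan_one(sequence, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sequence)))
    out <- rbind(out, scan_one(rc, "-"))
  }
  out$passes <- if (mode == "raw") out$raw_score >= raw_threshold
                else out$normalized_score >= normalized_threshold
  if (!both_strands) out$strand <- NULL
  rownames(out) <- NULL
  out[, c("start", "kmer", "raw_score", "normalized_score",
          intersect("strand", names(out)), "passes")]
}
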