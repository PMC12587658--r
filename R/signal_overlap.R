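#' Reciprocal overlap between two interval sets, pair by pair
#'
#' For aligned pairs `a[i], b[i]` computes the overlap in bp and the fraction
#' of each interval covered by the other. Strand is ignored; intervals on
#' different chromosomes overlap by 0 bp.
#'
#' @param a,b [GenomicRanges::GRanges] of equal length (length-1 operands are
#'   recycled).
#' @return Data frame with columns `overlap_bp`, `frac_a`, `frac_b`.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmax(0L, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
               pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
  ov[!same] <- 0L
  data.frame(overlap_bp = ov,
             frac_a = ov / IRanges::width(a),
             frac_b = ov / IRanges::width(b))
}

#' Intersect peaks with repeat annotations at a reciprocal-overlap fraction
#'
#' A (peak, repeat) pair is retained iff the overlap covers at least
#' `min_frac` of the peak AND at least `min_frac` of the repeat (inclusive
#' `>=` comparisons, matching bedtools reciprocal semantics where 50 bp
#' qualifies as 50% of a 100-bp feature). Candidate pairs are found with a
#' sorted interval-tree query; output is ordered by repeat then peak
#' coordinate.
#'
#' @param peaks,repeats [GenomicRanges::GRanges]; `name` metadata columns are
#'   carried into the output when present.
#' @param min_frac Minimum reciprocal overlap fraction in `[0, 1]`
#'   (default 0.5). `min_frac = 0` keeps every pair with >= 1 bp overlap.
#' @return Data frame with columns `peak` (index), `repeat.` (index),
#'   `peak_id`, `repeat_id`, `overlap_bp`, `frac_peak`, `frac_repeat`.
#' @export
intersect_annotations <- function(peaks, repeats, min_frac = 0.5) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  hits <- GenomicRanges::findOverlaps(peaks, repeats, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    ov <- IRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(peaks)[qi], GenomicRanges::granges(repeats)[si],
      ignore.strand = TRUE))
    fp <- ov / IRanges::width(peaks)[qi]
    fr <- ov / IRanges::width(repeats)[si]
    keep <- fp >= min_frac & fr >= min_frac
    qi <- qi[keep]; si <- si[keep]
    ov <- ov[keep]; fp <- fp[keep]; fr <- fr[keep]
  } else {
    ov <- integer(0); fp <- numeric(0); fr <- numeric(0)
  }
  id_of <- function(gr, i) {
    mc <- S4Vectors::mcols(gr)
    if ("name" %in% names(mc)) as.character(mc$name[i]) else as.character(i)
  }
  out <- data.frame(peak = qi, repeat. = si,
                    peak_id = id_of(peaks, qi),
                    repeat_id = id_of(repeats, si),
                    overlap_bp = ov, frac_peak = fp, frac_repeat = fr,
                    stringsAsFactors = FALSE)
  o <- order(as.character(GenomicRanges::seqnames(repeats))[out$repeat.],
             GenomicRanges::start(repeats)[out$repeat.],
             GenomicRanges::start(peaks)[out$peak])
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is removed iff it overlaps any blacklist interval by >= 1 bp
#' (any-overlap rule, mirroring common ENCODE practice). The number of
#' removed peaks is reported via `message()`.
#'
#' @param peaks,blacklist [GenomicRanges::GRanges].
#' @return The retained peaks.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0L) return(peaks)
  hit <- GenomicRanges::findOverlaps(peaks, blacklist, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hit))
  message("subtract_blacklist: removed ", length(drop), " of ",
          length(peaks), " peaks")
  if (length(drop)) peaks[-drop] else peaks
}

# Per-chromosome step-function integrator. Returns a function
# integral(chrom, a, b) of the track over 0-based half-open [a, b);
# uncovered positions contribute 0.
.track_integrator <- function(track) {
  chroms <- as.character(GenomicRanges::seqnames(track))
  by_chrom <- split(seq_along(track), chroms)
  tabs <- lapply(by_chrom, function(i) {
    s <- GenomicRanges::start(track)[i] - 1L  # 0-based
    e <- GenomicRanges::end(track)[i]
    v <- S4Vectors::mcols(track)$score[i]
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    # breakpoints and cumulative integral Q at each breakpoint
    bp <- sort(unique(c(s, e)))
    # value on [bp[j], bp[j+1]): v where inside a step else 0
    val <- numeric(length(bp) - 1L)
    ji <- findInterval(bp[-length(bp)], s)
    inside <- ji >= 1L & bp[-length(bp)] < e[pmax(ji, 1L)]
    val[inside] <- v[ji[inside]]
    Q <- c(0, cumsum(val * diff(bp)))
    list(bp = bp, Q = Q, val = val)
  })
  function(chrom, a, b) {
    tab <- tabs[[chrom]]
    if (is.null(tab)) return(numeric(length(a)))
    qat <- function(x) {
      x <- pmin(pmax(x, tab$bp[1L]), tab$bp[length(tab$bp)])
      j <- findInterval(x, tab$bp)
      j <- pmin(j, length(tab$bp) - 1L)
      tab$Q[j] + tab$val[j] * (x - tab$bp[j])
    }
    qat(b) - qat(a)
  }
}

#' Coverage signal matrix over intervals (scale-regions mode)
#'
#' Re-implements the deepTools computeMatrix scale-regions logic on bedGraph
#' input: the body of each interval is resampled into `n_bins` equal
#' sub-windows and each flank is binned at a fixed bp width; each bin value
#' is the length-weighted mean of the step values overlapping the bin, with
#' uncovered positions counting as 0. Rows for minus-strand intervals are
#' column-reversed. Intervals shorter than `n_bins` are retained with a
#' warning (bins then have fractional boundaries).
#'
#' @param track Coverage [GenomicRanges::GRanges] from [read_bedgraph()].
#' @param intervals [GenomicRanges::GRanges] of regions (rows).
#' @param n_bins Number of body bins (>= 1).
#' @param flank_bp Width of each flank in bp (0 disables flanks).
#' @param flank_bins Number of bins per flank (default `n_bins %/% 2`,
#'   minimum 1) so the flank bin width in bp is fixed across rows.
#' @return A list with `matrix` (rows = intervals, columns = upstream flank,
#'   body, downstream flank), `profile` (column means) and `col_type`
#'   (`"flank_up"`, `"body"`, `"flank_down"`).
#' @export
signal_matrix <- function(track, intervals, n_bins = 10L, flank_bp = 0L,
                          flank_bins = max(1L, n_bins %/% 2L)) {
  stopifnot(n_bins >= 1L, flank_bp >= 0L)
  if (any(IRanges::width(intervals) < n_bins))
    warning("interval(s) shorter than n_bins: fractional bin boundaries used")
  integ <- .track_integrator(track)
  use_flank <- flank_bp > 0L
  nf <- if (use_flank) flank_bins else 0L
  ncols <- n_bins + 2L * nf
  mat <- matrix(0, nrow = length(intervals), ncol = ncols)
  chroms <- as.character(GenomicRanges::seqnames(intervals))
  starts0 <- GenomicRanges::start(intervals) - 1
  ends0 <- as.numeric(GenomicRanges::end(intervals))
  strands <- as.character(GenomicRanges::strand(intervals))
  for (i in seq_along(intervals)) {
    edges_body <- seq(starts0[i], ends0[i], length.out = n_bins + 1L)
    edges <- edges_body
    if (use_flank) {
      fw <- flank_bp / nf
      up <- starts0[i] - rev(seq_len(nf)) * fw
      dn <- ends0[i] + seq_len(nf) * fw
      edges <- c(up, edges_body, dn)
    }
    a <- edges[-length(edges)]
    b <- edges[-1L]
    # clamp at chromosome origin: negative coordinates hold no signal
    vals <- integ(chroms[i], pmax(a, 0), pmax(b, 0)) / (b - a)
    if (strands[i] == "-") vals <- rev(vals)
    mat[i, ] <- vals
  }
  mc <- S4Vectors::mcols(intervals)
  rownames(mat) <- if ("name" %in% names(mc)) as.character(mc$name)
                   else as.character(seq_along(intervals))
  col_type <- c(rep("flank_up", nf), rep("body", n_bins),
                rep("flank_down", nf))
  list(matrix = mat, profile = colMeans(mat), col_type = col_type)
}
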