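#' Strand-aware upstream window of a gene TSS
#'
#' For a plus-strand gene the window is `[max(0, tss - w), tss)`; for a
#' minus-strand gene it is `[tss, tss + w)` (0-based half-open throughout).
#' Genes whose TSS sits at position 0 on the plus strand yield an empty
#' window and are dropped with a warning.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (`+` or `-`).
#' @param w Window width in bp (default 15000, the 15-kb upstream region
#'   searched for ERV enhancers).
#' @return A [GenomicRanges::GRanges] with metadata column `gene_id`.
#' @export
upstream_window <- function(genes, w = 15000L) {
  stopifnot(w > 0)
  need <- c("gene_id", "chrom", "tss", "strand")
  stopifnot(all(need %in% names(genes)))
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, pmax(0, genes$tss - w), genes$tss)
  end0 <- ifelse(plus, genes$tss, genes$tss + w)
  keep <- end0 > start0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " gene(s) with empty upstream window")
    genes <- genes[keep, , drop = FALSE]
    start0 <- start0[keep]; end0 <- end0[keep]
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = genes$strand)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  gr
}

#' Candidate ERV-gene pairs from strong enhancer calls
#'
#' Emits one row per (ERV, gene) combination where the repeat overlaps the
#' gene's upstream window by at least 1 bp and the repeat's enhancer class is
#' `"strong"`. A repeat may pair with several genes and vice versa.
#'
#' @param repeats [GenomicRanges::GRanges] with a `name` metadata column.
#' @param genes Data frame as for [upstream_window()].
#' @param calls Data frame with columns `sequence_id` and `enhancer_class`
#'   (from [classify_enhancers()]); repeats without a call are treated as
#'   non-enhancers.
#' @param w Upstream window width in bp (default 15000).
#' @return Data frame with columns `erv_id`, `gene_id`, `distance_bp` (TSS to
#'   nearest repeat edge; 0 if the repeat spans the TSS).
#' @export
find_candidate_pairs <- function(repeats, genes, calls, w = 15000L) {
  cls <- calls$enhancer_class[match(S4Vectors::mcols(repeats)$name,
                                    calls$sequence_id)]
  strong <- !is.na(cls) & cls == "strong"
  empty <- data.frame(erv_id = character(0), gene_id = character(0),
                      distance_bp = integer(0))
  if (!any(strong)) return(empty)
  reps <- repeats[strong]
  win <- upstream_window(genes, w)
  hits <- GenomicRanges::findOverlaps(reps, win, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  g <- genes[match(S4Vectors::mcols(win)$gene_id[si], genes$gene_id), ]
  rs0 <- GenomicRanges::start(reps)[qi] - 1L
  re0 <- GenomicRanges::end(reps)[qi]
  dist <- pmax(0L, pmax(rs0 - g$tss, g$tss - re0))
  out <- data.frame(erv_id = S4Vectors::mcols(reps)$name[qi],
                    gene_id = g$gene_id,
                    distance_bp = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$erv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with a t-distribution p-value
#'
#' Ties receive average ranks; rho is the Pearson correlation of the rank
#' vectors and the two-sided p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. A perfect correlation
#' (`rho = +/-1`) is reported with the smallest representable positive
#' p-value rather than 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 4` with finite values.
#' @return List with elements `rho` and `p_value`. Zero variance in either
#'   vector yields `rho = NA` with a warning.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p_value = min(p, 1))
}

#' Correlate candidate ERV-gene pairs across samples
#'
#' For every candidate pair, computes the Spearman correlation between the
#' ERV locus and the gene across all samples of the expression set, then
#' adjusts p-values over the candidate list with Benjamini-Hochberg.
#'
#' @param candidates Data frame from [find_candidate_pairs()].
#' @param expr An [expr_set()] whose features include every `erv_id` and
#'   `gene_id`.
#' @return The candidate data frame with added columns `rho`, `p_value`,
#'   `q_value`.
#' @export
pair_correlations <- function(candidates, expr) {
  feats <- rownames(expr$mat)
  missing <- setdiff(unique(c(candidates$erv_id, candidates$gene_id)), feats)
  if (length(missing))
    stop("feature '", missing[1L], "' missing from expression matrix")
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    spearman_rho(expr$mat[candidates$erv_id[i], ],
                 expr$mat[candidates$gene_id[i], ])
  })
  candidates$rho <- vapply(res, `[[`, numeric(1), "rho")
  candidates$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  candidates$q_value <- bh_adjust(candidates$p_value)
  candidates
}

#' Call strong ERV-gene pairs
#'
#' A pair is flagged strong iff `rho >= rho_min` and `q_value <= q_max`
#' (the correlation threshold and FDR level are conventions of this pipeline;
#' both are exposed here).
#'
#' @param pairs Data frame from [pair_correlations()].
#' @param rho_min Minimum Spearman rho (default 0.5).
#' @param q_max Maximum BH-adjusted q-value (default 0.05).
#' @return `pairs` with an added logical column `is_strong_pair`.
#' @export
call_strong_pairs <- function(pairs, rho_min = 0.5, q_max = 0.05) {
  pairs$is_strong_pair <- !is.na(pairs$rho) & pairs$rho >= rho_min &
    pairs$q_value <= q_max
  message("call_strong_pairs: ", sum(pairs$is_strong_pair), " of ",
          nrow(pairs), " pairs called strong")
  pairs
}

#' Cluster the pairwise Spearman correlation matrix with k-means
#'
#' Builds the feature x feature Spearman correlation matrix over the given
#' expression features and partitions its rows with k-means (Euclidean
#' distance, seeded restarts).
#'
#' @param feature_ids Features (genes and/or ERV loci) to correlate.
#' @param expr An [expr_set()].
#' @param k Number of clusters (2 <= k <= number of features).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return List with `labels` (named integer vector), `wcss` (total
#'   within-cluster sum of squares) and `correlation` (the matrix clustered).
#' @export
cluster_correlation_matrix <- function(feature_ids, expr, k, seed = 1L,
                                       nstart = 10L) {
  stopifnot(k >= 2L)
  if (k > length(feature_ids))
    stop("k = ", k, " exceeds number of features (", length(feature_ids), ")")
  sub <- expr$mat[feature_ids, , drop = FALSE]
  rmat <- stats::cor(t(sub), method = "spearman")
  if (k == length(feature_ids)) {   # degenerate: one feature per cluster
    return(list(labels = stats::setNames(seq_len(k), feature_ids),
                wcss = 0, correlation = rmat))
  }
  set.seed(seed)
  km <- stats::kmeans(rmat, centers = k, nstart = nstart, iter.max = 100L)
  list(labels = stats::setNames(km$cluster, feature_ids),
       wcss = km$tot.withinss, correlation = rmat)
}
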