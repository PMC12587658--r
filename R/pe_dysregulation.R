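#' Filter a differential-expression table
#'
#' Keeps genes with `padj < alpha` and a log2 fold-change above `lfc_min`;
#' both comparisons are strict, so a row at exactly `padj = alpha` is
#' excluded. In `absolute` mode the fold-change criterion is
#' `|log2fc| > lfc_min` (dysregulation in either direction).
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, `p`, `padj`.
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param lfc_min log2 fold-change cutoff (default 1).
#' @param absolute If `TRUE` (default), filter on `|log2fc|`.
#' @return The filtered table (a subset of the input rows).
#' @export
filter_degs <- function(table, alpha = 0.05, lfc_min = 1, absolute = TRUE) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  lfc <- if (absolute) abs(table$log2fc) else table$log2fc
  keep <- table$padj < alpha & lfc > lfc_min
  message("filter_degs: ", sum(keep), " of ", nrow(table), " genes pass")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; the input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-batch location/scale centering of an expression set
#'
#' A transparent stand-in for empirical-Bayes batch correction: within each
#' batch every gene is standardized to mean 0 / unit variance, then restored
#' to the pooled (all-sample) gene mean and pooled gene standard deviation.
#' Genes with zero variance inside a batch skip the scale step for that batch
#' (location only) and are flagged. A principal-component diagnostic reports
#' the variance explained by the batch label before and after adjustment.
#'
#' @param expr An [expr_set()] with >= 2 samples per batch.
#' @return A list with `expr` (the adjusted [expr_set()]), `flagged_genes`
#'   (genes with a zero-variance batch) and `batch_r2` (named vector,
#'   fraction of PC1 variance explained by batch before/after).
#' @export
batch_center <- function(expr) {
  mat <- expr$mat
  batch <- as.factor(expr$meta$batch)
  if (any(table(batch) < 2L)) stop("each batch needs >= 2 samples")
  pooled_mean <- rowMeans(mat)
  pooled_sd <- apply(mat, 1L, stats::sd)
  out <- mat
  flagged <- character(0)
  for (b in levels(batch)) {
    cols <- which(batch == b)
    sub <- mat[, cols, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    zero <- s == 0
    flagged <- union(flagged, rownames(mat)[zero])
    scale_to <- ifelse(zero | pooled_sd == 0, 1, pooled_sd / ifelse(zero, 1, s))
    out[, cols] <- (sub - m) * scale_to + pooled_mean
  }
  r2 <- function(m) {
    if (nlevels(batch) < 2L) return(NA_real_)
    pc1 <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)$x[, 1L]
    summary(stats::lm(pc1 ~ batch))$r.squared
  }
  list(expr = expr_set(out, expr$meta),
       flagged_genes = flagged,
       batch_r2 = c(before = r2(mat), after = r2(out)))
}

#' Per-gene relative abundance
#'
#' The ratio of a gene's expression in each sample to that gene's mean across
#' samples. Because a ratio of log values is not a fold measure, log-scale
#' input is unlogged first (`linear = 2^x - 1` for log2(TPM+1) input); the
#' per-gene mean of the ratios is exactly 1 on the scale the ratio is
#' computed.
#'
#' @param expr An [expr_set()].
#' @param from_log If `TRUE` (default), values are log2(TPM+1) and are
#'   converted back to the linear TPM scale before the ratio is taken.
#' @return A list with `ratio` (matrix, same shape as the input) and
#'   `flagged_genes` (genes with zero mean, whose ratios are `NA`).
#' @export
relative_abundance <- function(expr, from_log = TRUE) {
  x <- if (from_log) pmax(2^expr$mat - 1, 0) else expr$mat
  m <- rowMeans(x)
  ratio <- x / m
  flagged <- rownames(x)[m <= 0]
  ratio[m <= 0, ] <- NA_real_
  list(ratio = ratio, flagged_genes = flagged)
}

#' Samples with relatively high expression of one gene
#'
#' Operationalizes "relatively higher" as a relative abundance strictly above
#' `threshold` (default 1, i.e. above the gene's cross-sample mean).
#'
#' @param ra Result of [relative_abundance()].
#' @param gene_id Gene to inspect.
#' @param threshold Ratio cutoff (default 1).
#' @return Character vector of sample ids flagged high.
#' @export
flag_high <- function(ra, gene_id, threshold = 1.0) {
  if (!gene_id %in% rownames(ra$ratio))
    stop("unknown gene '", gene_id, "'")
  r <- ra$ratio[gene_id, ]
  colnames(ra$ratio)[!is.na(r) & r > threshold]
}

#' One-sided upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: from an urn of `N` samples
#' of which `K` are flagged high, `n` are drawn (the PE group) and `k` of
#' those are flagged. Computed with log-binomial arithmetic (stable for
#' N up to at least 10,000).
#'
#' @param N Total samples. @param K Samples flagged high.
#' @param n Samples in the group of interest. @param k Flagged samples
#'   within that group.
#' @return The upper-tail p-value.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0, K <= N, n <= N,
            k <= min(K, n))
  if (k == 0) return(1.0)
  j <- k:min(K, n)
  # require enough failures to fill the draw: n - j <= N - K
  j <- j[n - j <= N - K]
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

#' Intersection and correlation of two DE tables
#'
#' Filters both tables with [filter_degs()] in absolute mode, intersects the
#' surviving gene sets, and computes the Spearman correlation of the log2
#' fold-changes over the shared genes.
#'
#' @param a,b DE tables (see [filter_degs()]).
#' @param alpha,lfc_min Filter parameters passed to [filter_degs()].
#' @return List with `n_common`, `common_ids`, `rho`, `p_value` (`rho` is
#'   `NA` when fewer than 4 genes are shared).
#' @export
common_deg_correlation <- function(a, b, alpha = 0.05, lfc_min = 1) {
  fa <- filter_degs(a, alpha, lfc_min, absolute = TRUE)
  fb <- filter_degs(b, alpha, lfc_min, absolute = TRUE)
  ids <- intersect(fa$gene_id, fb$gene_id)
  if (length(ids) < 4L)
    return(list(n_common = length(ids), common_ids = ids,
                rho = NA_real_, p_value = NA_real_))
  s <- spearman_rho(fa$log2fc[match(ids, fa$gene_id)],
                    fb$log2fc[match(ids, fb$gene_id)])
  list(n_common = length(ids), common_ids = ids,
       rho = s$rho, p_value = s$p_value)
}

#' Convenience two-group differential expression (Wilcoxon + BH)
#'
#' Builds a DE table from an expression set for synthetic-data runs; real
#' analyses should supply DE tables from a dedicated caller. The log2
#' fold-change is the PE-minus-control difference of group means on the
#' log2 scale.
#'
#' @param expr An [expr_set()].
#' @return A DE table with columns `gene_id`, `log2fc`, `p`, `padj`.
#' @export
de_wilcoxon <- function(expr) {
  pe <- expr$meta$condition == "PE"
  if (!any(pe) || all(pe)) stop("need both conditions for DE")
  p <- apply(expr$mat, 1L, function(v) {
    stats::wilcox.test(v[pe], v[!pe], exact = FALSE)$p.value
  })
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(expr$mat),
             log2fc = rowMeans(expr$mat[, pe, drop = FALSE]) -
               rowMeans(expr$mat[, !pe, drop = FALSE]),
             p = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE)
}
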