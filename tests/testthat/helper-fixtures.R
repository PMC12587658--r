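# Shared small fixtures. Everything is generated in code at test time; the
# tiny CNN settings keep unit tests fast while the acceptance tests use the
# package defaults.

tiny_sim <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chrom = 2L, chrom_length = 200000L,
             n_repeats = 20L, fraction_enhancer_repeats = 0.5,
             repeat_length = 300L, n_genes = 10L, n_planted_pairs = 5L,
             n_pos = 60L, n_neg = 60L, seq_length = 300L, ...)
}

tiny_cnn <- function(seed = 1L, ...) {
  cnn_config(input_length = 300L, filters1 = 8L, kernel1 = 8L, pool1 = 4L,
             filters2 = 8L, kernel2 = 4L, dense_units = 8L, dropout = 0,
             epochs = 8L, batch_size = 16L, seed = seed, ...)
}

subset_encoded <- function(e, i) {
  out <- list(onehot = e$onehot[, , i, drop = FALSE], gc = e$gc[i],
              ids = e$ids[i], all_n = e$all_n[i])
  if (!is.null(e$label)) out$label <- e$label[i]
  out
}

random_granges <- function(n, n_chrom = 3L, max_pos = 10000L,
                           max_len = 500L) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, start + len - 1L))
  S4Vectors::mcols(gr)$name <- sprintf("iv%04d", seq_len(n))
  gr
}

# O(n*m) all-pairs reference for reciprocal-overlap intersection (one
# explicit pass per query, each checked against every subject)
brute_force_intersect <- function(peaks, repeats, min_frac) {
  pc <- as.character(GenomicRanges::seqnames(peaks))
  rc <- as.character(GenomicRanges::seqnames(repeats))
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  rs <- GenomicRanges::start(repeats); re <- GenomicRanges::end(repeats)
  pw <- IRanges::width(peaks); rw <- IRanges::width(repeats)
  res <- list()
  for (i in seq_along(peaks)) {
    ov <- pmin(pe[i], re) - pmax(ps[i], rs) + 1L
    keep <- rc == pc[i] & ov >= 1L &
      (min_frac == 0 | (ov / pw[i] >= min_frac & ov / rw >= min_frac))
    j <- which(keep)
    if (length(j))
      res[[length(res) + 1L]] <- cbind(i, j)
  }
  if (!length(res)) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, res)
}
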