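test_that("upstream windows follow strand and clamp at the origin", {
  genes <- data.frame(gene_id = c("g+", "g-", "gclamp"),
                      chrom = "chr1",
                      tss = c(50000L, 50000L, 4000L),
                      strand = c("+", "-", "+"))
  win <- upstream_window(genes, 15000L)
  # 0-based half-open expectations translated to 1-based GRanges
  expect_equal(GenomicRanges::start(win), c(35001L, 50001L, 1L))
  expect_equal(GenomicRanges::end(win), c(50000L, 65000L, 4000L))
  expect_error(upstream_window(transform(genes, tss = -1L)), "tss")
  expect_error(upstream_window(transform(genes, strand = ".")), "strand")
  # tss at the origin on + strand yields no window
  g0 <- data.frame(gene_id = "g0", chrom = "chr1", tss = 0L, strand = "+")
  expect_warning(w0 <- upstream_window(g0), "empty")
  expect_length(w0, 0L)
})

test_that("candidate pairs require a strong call and >= 1 bp window overlap", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 50000L,
                      strand = "+")
  # repeat ending exactly at the window edge (0-based end 35000) is out;
  # one bp further in is a candidate
  reps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(34401, 34402, 50001),
                                                  c(35000, 35001, 50600)))
  S4Vectors::mcols(reps)$name <- c("out", "in", "downstream")
  calls <- data.frame(sequence_id = c("out", "in", "downstream"),
                      enhancer_class = "strong")
  got <- find_candidate_pairs(reps, genes, calls, 15000L)
  expect_equal(got$erv_id, "in")
  expect_equal(got$distance_bp, 14999L)
  # no strong calls -> empty
  calls$enhancer_class <- "weak"
  expect_equal(nrow(find_candidate_pairs(reps, genes, calls, 15000L)), 0L)
})

test_that("all planted pairs appear among synthetic candidates", {
  g <- simulate_genome(tiny_sim(seed = 12L))
  calls <- data.frame(
    sequence_id = S4Vectors::mcols(g$repeats)$name,
    enhancer_class = ifelse(S4Vectors::mcols(g$repeats)$name %in%
                              g$truth$enhancer_repeat_ids, "strong", "non"))
  cand <- find_candidate_pairs(g$repeats, g$genes, calls, 15000L)
  expect_true(all(paste(g$truth$planted_pairs$erv_id,
                        g$truth$planted_pairs$gene_id) %in%
                    paste(cand$erv_id, cand$gene_id)))
})

test_that("Spearman matches the hand-ranked average-rank oracle", {
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  # hand ranks: x -> (1, 2.5, 2.5, 4), y -> (1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_rho(x, y)
  expect_equal(got$rho, oracle)
  # p from the two-sided t approximation
  tval <- oracle * sqrt(2 / (1 - oracle^2))
  expect_equal(got$p_value, 2 * pt(abs(tval), df = 2, lower.tail = FALSE))
  # perfect correlations and degenerate input
  expect_equal(spearman_rho(1:10, 1:10)$rho, 1)
  expect_gt(spearman_rho(1:10, 1:10)$p_value, 0)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  expect_warning(res <- spearman_rho(rep(1, 5), 1:5), "variance")
  expect_true(is.na(res$rho))
})

test_that("pair correlation recovers planted pairs and permutation nulls them", {
  cfg <- sim_config(seed = 13L, n_pe = 20L, n_control = 20L)
  ervs <- sprintf("E%02d", 1:30); genes <- sprintf("G%02d", 1:30)
  truth <- list(planted_pairs = data.frame(erv_id = ervs[1:20],
                                           gene_id = genes[1:20]))
  ex <- simulate_expression(cfg, truth, genes, ervs)
  expr <- batch_center(ex$expr)$expr
  cand <- data.frame(erv_id = ervs[1:20], gene_id = genes[1:20],
                     distance_bp = 0L)
  pairs <- pair_correlations(cand, expr)
  expect_true(mean(pairs$rho >= 0.7) >= 0.9)
  # permuting sample labels of the ERV rows centres the rho distribution at 0
  set.seed(1)
  perm <- expr
  perm$mat[ervs, ] <- perm$mat[ervs, sample(ncol(perm$mat))]
  pairs_perm <- pair_correlations(cand, perm)
  expect_lt(abs(mean(pairs_perm$rho)), 0.15)
  # missing feature is named
  bad <- data.frame(erv_id = "nope", gene_id = "G01", distance_bp = 0L)
  expect_error(pair_correlations(bad, expr), "nope")
})

test_that("BH adjustment on the textbook example and strong-call monotonicity", {
  pairs <- data.frame(erv_id = letters[1:4], gene_id = LETTERS[1:4],
                      rho = c(0.9, 0.8, 0.7, 0.6),
                      p_value = c(0.01, 0.02, 0.03, 0.04))
  pairs$q_value <- bh_adjust(pairs$p_value)
  expect_equal(pairs$q_value, rep(0.04, 4))
  out1 <- suppressMessages(call_strong_pairs(pairs, rho_min = 0.5,
                                             q_max = 0.05))
  expect_equal(sum(out1$is_strong_pair), 4L)
  out2 <- suppressMessages(call_strong_pairs(pairs, rho_min = 0.5,
                                             q_max = 0.03))
  expect_lte(sum(out2$is_strong_pair), sum(out1$is_strong_pair))
  out3 <- suppressMessages(call_strong_pairs(pairs, rho_min = 1.01))
  expect_equal(sum(out3$is_strong_pair), 0L)
})

test_that("k-means on the correlation matrix separates planted blocks", {
  cfg <- sim_config(seed = 14L, n_pe = 20L, n_control = 20L,
                    planted_pair_rho = 0.9)
  # two blocks of mutually correlated features: use planted pairs to build
  # block structure (erv_i, gene_i) then check pair members co-cluster
  ervs <- sprintf("E%02d", 1:2); genes <- sprintf("G%02d", 1:2)
  truth <- list(planted_pairs = data.frame(erv_id = ervs, gene_id = genes))
  ex <- simulate_expression(cfg, truth, genes, ervs)
  expr <- batch_center(ex$expr)$expr
  cl <- cluster_correlation_matrix(c(ervs, genes), expr, k = 2L, seed = 5L)
  expect_equal(cl$labels[["E01"]], cl$labels[["G01"]])
  expect_equal(cl$labels[["E02"]], cl$labels[["G02"]])
  expect_false(cl$labels[["E01"]] == cl$labels[["E02"]])
  # k = number of features -> singleton clusters with zero WCSS
  cl2 <- cluster_correlation_matrix(c(ervs, genes), expr, k = 4L, seed = 5L)
  expect_equal(cl2$wcss, 0)
  expect_length(unique(cl2$labels), 4L)
  # seeded determinism
  cl3 <- cluster_correlation_matrix(c(ervs, genes), expr, k = 2L, seed = 5L)
  expect_identical(cl$labels, cl3$labels)
  expect_error(cluster_correlation_matrix(ervs, expr, k = 3L), "exceeds")
})
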