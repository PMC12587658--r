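test_that("DEG filtering is strict, subsetting and idempotent", {
  empty <- data.frame(gene_id = character(0), log2fc = numeric(0),
                      p = numeric(0), padj = numeric(0))
  expect_equal(nrow(filter_degs(empty)), 0L)
  set.seed(40)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200, 0, 2),
                    p = runif(200), padj = runif(200))
  f1 <- filter_degs(tab)
  expect_true(all(f1$padj < 0.05 & abs(f1$log2fc) > 1))
  expect_true(all(f1$gene_id %in% tab$gene_id))
  expect_equal(filter_degs(f1), f1)
  # directional mode drops negative fold-changes
  fd <- filter_degs(tab, absolute = FALSE)
  expect_true(all(fd$log2fc > 1))
  # boundary row exactly at alpha is excluded
  b <- data.frame(gene_id = "x", log2fc = 2, p = 0.01, padj = 0.05)
  expect_equal(nrow(filter_degs(b)), 0L)
})

test_that("BH matches the direct min-over-tail formula on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  direct <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m))
      adj[o[i]] <- min(1, min(m * p[o[i:m]] / seq(i, m)))
    adj
  }
  set.seed(41)
  for (rep in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), direct(p))
  }
  # monotone non-decreasing along sorted p
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
})

test_that("batch centering is the identity on one batch and removes shifts", {
  set.seed(42)
  mat <- matrix(rnorm(200, 4), 10, 20,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("s%02d", 1:20)))
  meta1 <- data.frame(sample = colnames(mat),
                      condition = rep(c("PE", "control"), each = 10),
                      batch = 1L)
  out1 <- batch_center(expr_set(mat, meta1))
  expect_equal(out1$expr$mat, mat, tolerance = 1e-9)
  # two batches with an additive shift of 2, balanced across condition
  meta2 <- meta1
  meta2$batch <- rep(c(1L, 2L), 10)
  mat2 <- mat
  mat2[, meta2$batch == 2L] <- mat2[, meta2$batch == 2L] + 2
  out2 <- batch_center(expr_set(mat2, meta2))
  b1 <- rowMeans(out2$expr$mat[, meta2$batch == 1L])
  b2 <- rowMeans(out2$expr$mat[, meta2$batch == 2L])
  expect_true(all(abs(b1 - b2) < 0.05))
  expect_gt(out2$batch_r2["before"], out2$batch_r2["after"])
  # condition-linked signal survives adjustment
  mat3 <- mat2
  mat3["g01", meta2$condition == "PE"] <-
    mat3["g01", meta2$condition == "PE"] + 1.5
  out3 <- batch_center(expr_set(mat3, meta2))
  pre_diff <- mean(mat3["g01", meta2$condition == "PE"]) -
    mean(mat3["g01", meta2$condition == "control"]) - 2 * 0  # batches balanced
  post_diff <- mean(out3$expr$mat["g01", meta2$condition == "PE"]) -
    mean(out3$expr$mat["g01", meta2$condition == "control"])
  expect_lt(abs(post_diff - pre_diff) / abs(pre_diff), 0.35)
  expect_error(batch_center(expr_set(mat, transform(meta1, batch = 1:20))),
               ">= 2 samples")
})

test_that("relative abundance has unit per-gene mean and hand-checked values", {
  mat <- matrix(log2(c(2, 4) + 1), 1, 2,
                dimnames = list("g", c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"),
                     condition = c("PE", "control"), batch = 1L)
  # linear values 2 and 4, mean 3 -> ratios 2/3, 4/3
  ra <- relative_abundance(expr_set(mat, meta))
  expect_equal(unname(ra$ratio[1, ]), c(2 / 3, 4 / 3))
  # constant gene -> ratios exactly 1, so no sample is strictly high
  mat2 <- matrix(3, 2, 4, dimnames = list(c("g1", "g2"),
                                          sprintf("s%d", 1:4)))
  meta2 <- data.frame(sample = sprintf("s%d", 1:4),
                      condition = rep(c("PE", "control"), 2), batch = 1L)
  ra2 <- relative_abundance(expr_set(mat2, meta2))
  expect_true(all(ra2$ratio == 1))
  expect_length(flag_high(ra2, "g1"), 0L)
  expect_error(flag_high(ra2, "nope"), "unknown gene")
  # unit mean per gene on random matrices
  set.seed(43)
  mat3 <- matrix(rnorm(300, 4), 15, 20,
                 dimnames = list(sprintf("g%02d", 1:15),
                                 sprintf("s%02d", 1:20)))
  meta3 <- data.frame(sample = colnames(mat3),
                      condition = rep(c("PE", "control"), 10), batch = 1L)
  ra3 <- relative_abundance(expr_set(mat3, meta3))
  expect_equal(unname(rowMeans(ra3$ratio)), rep(1, 15), tolerance = 1e-9)
  # threshold at infinity flags nothing
  expect_length(flag_high(ra3, "g01", threshold = Inf), 0L)
})

test_that("hypergeometric tail matches enumeration and is exchange-symmetric", {
  expect_equal(hypergeom_enrichment(10, 5, 5, 0), 1.0)
  expect_equal(hypergeom_enrichment(10, 5, 5, 5), 1 / choose(10, 5))
  enum <- function(N, K, n, k) {
    j <- k:min(K, n)
    j <- j[n - j <= N - K]
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(44)
  for (rep in 1:300) {
    N <- sample(1:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k_lo <- max(0L, K + n - N)
    k <- sample(k_lo:min(K, n), 1)
    p <- hypergeom_enrichment(N, K, n, k)
    expect_equal(p, min(1, enum(N, K, n, k)), tolerance = 1e-12)
    # exchange symmetry in (K, n)
    expect_equal(p, hypergeom_enrichment(N, n, K, k), tolerance = 1e-12)
    # agreement with the survival function of the standard distribution
    expect_equal(p, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # no overflow at large N
  expect_true(is.finite(hypergeom_enrichment(10000, 400, 500, 50)))
  expect_error(hypergeom_enrichment(10, 12, 5, 3), "K <= N")
})

test_that("flagging recovers planted high samples better than chance", {
  cfg <- sim_config(seed = 45L)
  ervs <- sprintf("E%02d", 1:2); genes <- sprintf("G%02d", 1:3)
  ex <- simulate_expression(cfg, list(planted_pairs =
    data.frame(erv_id = ervs[1], gene_id = genes[1])), genes, ervs)
  expr <- batch_center(ex$expr)$expr
  ra <- relative_abundance(expr)
  high <- flag_high(ra, ex$truth$overexpressed_gene)
  planted <- c(ex$truth$pe_high_samples, ex$truth$control_high_samples)
  flag_rate_planted <- mean(planted %in% high)
  flag_rate_other <- mean(setdiff(colnames(expr$mat), planted) %in% high)
  expect_gt(flag_rate_planted, flag_rate_other)
})

test_that("common-DEG correlation handles identity and disjoint inputs", {
  set.seed(46)
  a <- data.frame(gene_id = sprintf("g%02d", 1:30),
                  log2fc = rnorm(30, 0, 2),
                  p = runif(30, 0, 0.05), padj = runif(30, 0, 0.04))
  got <- common_deg_correlation(a, a)
  expect_equal(got$rho, 1)
  expect_equal(got$n_common, sum(abs(a$log2fc) > 1))
  b <- a
  b$gene_id <- sprintf("h%02d", 1:30)
  got2 <- common_deg_correlation(a, b)
  expect_equal(got2$n_common, 0L)
  expect_true(is.na(got2$rho))
})
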