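test_that("pseudocount normalization matches hand arithmetic", {
  counts <- matrix(c(3, 0, 0, 1), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  probs <- normalize_pwm(counts, pseudocount = 1)
  expect_equal(unname(probs[, 1]), c(0.5, 0.125, 0.125, 0.25))
  # symmetric counts -> uniform
  expect_equal(unname(normalize_pwm(matrix(5, 4, 3))[, 2]), rep(0.25, 4))
  # column stochasticity on arbitrary counts
  set.seed(30)
  cm <- matrix(rpois(4 * 7, 20), 4, 7)
  expect_equal(colSums(normalize_pwm(cm)), rep(1, 7), tolerance = 1e-9)
  # zero pseudocount with a zero column fails the invariant
  expect_error(normalize_pwm(matrix(0, 4, 2), pseudocount = 0), "total")
  expect_error(normalize_pwm(matrix(-1, 4, 1)), "non-negative")
})

test_that("window scoring is additive and handles uniform PWMs and N", {
  unif <- matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  s <- score_window(unif, "ACGTACG")
  expect_equal(s, 7 * log(0.25 + 1e-6), tolerance = 1e-12)
  # N contributes the uniform probability
  expect_equal(score_window(unif, "ACGNACG"), s)
  # column separability: concatenated PWMs sum their scores
  pwm <- normalize_pwm(consensus_pwm_counts("TGACTCA"))
  both <- cbind(pwm, pwm)
  expect_equal(score_window(both, "TGACTCATGACTCA"),
               2 * score_window(pwm, "TGACTCA"))
  expect_error(score_window(pwm, "ACGT"), "length")
})

test_that("consensus attains the exhaustive maximum over all 16384 7-mers", {
  pwm <- normalize_pwm(consensus_pwm_counts("TGACTCA", strength = 0.8))
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), 7),
                                       stringsAsFactors = FALSE))
  expect_length(kmers, 16384L)
  lp <- log(pwm + 1e-6)
  scores <- vapply(strsplit(kmers, ""), function(ch)
    sum(lp[cbind(match(ch, bases), 1:7)]), numeric(1))
  rg <- pwm_score_range(pwm)
  expect_equal(max(scores), unname(rg["max"]))
  expect_equal(min(scores), unname(rg["min"]))
  expect_equal(score_window(pwm, "TGACTCA"), max(scores))
  # normalized scores: consensus 1, anti-consensus 0, all within [0, 1]
  ns <- normalize_score(scores, pwm)
  expect_true(all(ns >= 0 & ns <= 1))
  expect_equal(normalize_score(score_window(pwm, "TGACTCA"), pwm), 1)
  anti <- paste0(bases[apply(pwm, 2, which.min)], collapse = "")
  expect_equal(normalize_score(score_window(pwm, anti), pwm), 0)
})

test_that("uniform PWM has zero score range and warns on normalization", {
  unif <- matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_warning(ns <- normalize_score(-9.7, unif), "uniform")
  expect_equal(ns, 1)
})

test_that("scanning reports every window and flags passers correctly", {
  pwm <- normalize_pwm(consensus_pwm_counts("TGACTCA"))
  # exact consensus sequence: one window, normalized 1, passes
  h <- scan_sequence("TGACTCA", pwm)
  expect_equal(nrow(h), 1L)
  expect_equal(h$normalized_score, 1)
  expect_true(h$passes)
  # shorter than the window: zero windows, not an error
  expect_equal(nrow(scan_sequence("TGACTC", pwm)), 0L)
  # brute-force re-scoring of every window on a random 200-mer
  set.seed(31)
  s <- paste0(sample(c("A", "C", "G", "T", "N"), 200, TRUE,
                     prob = c(.24, .24, .24, .24, .04)), collapse = "")
  h <- scan_sequence(s, pwm)
  expect_equal(nrow(h), 200L - 7L + 1L)
  for (i in sample(nrow(h), 25L)) {
    expect_equal(h$raw_score[i], score_window(pwm, h$kmer[i]))
    expect_equal(h$normalized_score[i],
                 normalize_score(h$raw_score[i], pwm))
  }
  expect_equal(h$passes, h$normalized_score >= 0.5)
})

test_that("raising thresholds never increases the passing count", {
  pwm <- normalize_pwm(consensus_pwm_counts())
  set.seed(32)
  s <- paste0(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  n_pass <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    sum(scan_sequence(s, pwm, normalized_threshold = thr)$passes), numeric(1))
  expect_true(all(diff(n_pass) <= 0))
  n_raw <- vapply(c(-20, -10, -5, 0), function(thr)
    sum(scan_sequence(s, pwm, mode = "raw", raw_threshold = thr)$passes),
    numeric(1))
  expect_true(all(diff(n_raw) <= 0))
})

test_that("drop-n and both-strand options behave", {
  pwm <- normalize_pwm(consensus_pwm_counts())
  h <- scan_sequence("TGACTCAN", pwm, drop_n_windows = TRUE)
  expect_equal(nrow(h), 1L)   # the N-containing window is dropped
  # a non-palindromic consensus: the reverse complement of the motif is
  # found only when both strands are scanned (AP-1 itself is nearly
  # palindromic, so an asymmetric motif is used for this check)
  pwm_a <- normalize_pwm(consensus_pwm_counts("AAACCCG"))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet("AAACCCG")))
  expect_false(any(scan_sequence(rc, pwm_a)$passes))
  h2 <- scan_sequence(rc, pwm_a, both_strands = TRUE)
  expect_true(any(h2$passes & h2$strand == "-"))
})

test_that("planted training positives carry >= 2 passing windows", {
  cfg <- sim_config(n_pos = 40L, n_neg = 5L)
  tr <- simulate_training_set(cfg)
  pwm <- normalize_pwm(consensus_pwm_counts(cfg$motif))
  pos <- as.character(tr[S4Vectors::mcols(tr)$label == 1L])
  n_pass <- vapply(pos, function(s) sum(scan_sequence(s, pwm)$passes),
                   numeric(1))
  expect_true(all(n_pass >= 2))
})

test_that("JASPAR count files parse in both plain and bracketed formats", {
  tf <- withr::local_tempfile()
  writeLines(c(">MA0000.0 SYN", "A [ 10 0 5 ]", "C [ 0 20 5 ]",
               "G [ 5 0 5 ]", "T [ 5 0 5 ]"), tf)
  m <- read_jaspar(tf)
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m["C", 2]), 20)
  writeLines(c("10 0 5", "0 20 5", "5 0 5", "5 0 5"), tf)
  expect_equal(read_jaspar(tf), m)
  writeLines(c("1 2", "3"), tf)
  expect_error(read_jaspar(tf), "4 count rows")
})
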