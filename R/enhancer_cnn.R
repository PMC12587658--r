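#' One-hot encode DNA sequences with a GC side feature
#'
#' Sequences longer than `L` are center-cropped; shorter ones are
#' symmetrically zero-padded. `N` becomes an all-zero column. The GC fraction
#' is computed over the non-N bases of the original, uncropped sequence so
#' cropping cannot change it; an all-N sequence gets `gc = 0` and is flagged.
#'
#' @param seqs A [Biostrings::DNAStringSet], or character vector of sequences
#'   over `A,C,G,T,N`.
#' @param L Target encoded length.
#' @return List with `onehot` (array `4 x L x n`, rows A,C,G,T), `gc`
#'   (numeric), `ids` (names), `all_n` (logical flag per sequence) and, when
#'   the input carries a `label` metadata column, `label`.
#' @export
encode_sequences <- function(seqs, L) {
  label <- NULL
  if (methods::is(seqs, "XStringSet")) {
    mc <- S4Vectors::mcols(seqs)
    if (!is.null(mc) && "label" %in% names(mc)) label <- mc$label
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(length(seqs) > 0L, all(nchar(seqs) > 0L))
  n <- length(seqs)
  ids <- if (is.null(names(seqs))) as.character(seq_len(n)) else names(seqs)
  onehot <- array(0, dim = c(4L, L, n))
  gc <- numeric(n)
  all_n <- logical(n)
  for (i in seq_len(n)) {
    chars <- strsplit(toupper(seqs[[i]]), "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T"))
    acgt <- sum(!is.na(idx))
    if (acgt == 0L) {
      gc[i] <- 0
      all_n[i] <- TRUE
      warning("sequence '", ids[i], "' is all-N; gc set to 0")
    } else {
      gc[i] <- sum(chars %in% c("G", "C")) / acgt
    }
    len <- length(idx)
    if (len > L) {                      # center crop
      off <- (len - L) %/% 2L
      idx <- idx[(off + 1L):(off + L)]
      cols <- seq_len(L)
    } else {                            # symmetric pad
      pad <- (L - len) %/% 2L
      cols <- pad + seq_len(len)
    }
    keep <- !is.na(idx)
    onehot[cbind(idx[keep], cols[keep], i)] <- 1
  }
  out <- list(onehot = onehot, gc = gc, ids = ids, all_n = all_n)
  if (!is.null(label)) out$label <- as.integer(label)
  out
}

#' Classifier configuration
#'
#' Defaults follow a minimal motif-detector design: two convolution blocks
#' (32 filters x width 12 with max-pool 4, then 64 filters x width 8), global
#' max-pooling, the standardized GC scalar concatenated before a 32-unit
#' dense layer, and a sigmoid output. Class cut-points (`strong_threshold`,
#' `weak_threshold`) bin the probability score into strong / weak /
#' non-enhancer calls.
#'
#' @param input_length Encoded sequence length L (default 600).
#' @param filters1,kernel1,pool1 First convolution block.
#' @param filters2,kernel2 Second convolution block (followed by global
#'   max-pool).
#' @param dense_units Dense layer width.
#' @param dropout Dropout rate on the dense layer during training.
#' @param use_gc Whether the GC feature is wired into the dense layer.
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param test_fraction Held-out fraction used by [split_train_test()].
#' @param strong_threshold,weak_threshold Probability cut-points, inclusive
#'   at the lower edge of each class (`0 < weak < strong < 1`).
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(input_length = 600L,
                       filters1 = 32L, kernel1 = 12L, pool1 = 4L,
                       filters2 = 64L, kernel2 = 8L,
                       dense_units = 32L, dropout = 0.2, use_gc = TRUE,
                       learning_rate = 1e-3, epochs = 30L, batch_size = 32L,
                       seed = 1L, test_fraction = 0.2,
                       strong_threshold = 0.8, weak_threshold = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$weak_threshold > 0, cfg$weak_threshold < cfg$strong_threshold,
            cfg$strong_threshold < 1, cfg$epochs >= 1, cfg$batch_size >= 1,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$test_fraction > 0,
            cfg$test_fraction < 1)
  structure(cfg, class = "cnn_config")
}

#' Label-stratified train/test split
#'
#' @param labels Integer 0/1 vector (both classes must be present; >= 10
#'   examples).
#' @param test_fraction Fraction per class held out.
#' @param seed Seed making the split reproducible.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering the input).
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(length(labels) >= 10L)
  if (length(unique(labels)) < 2L)
    stop("both labels must be present for a stratified split")
  set.seed(seed)
  test <- unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, round(length(idx) * test_fraction))
  }))
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Train the enhancer CNN
#'
#' Minimises binary cross-entropy with Adam over seeded mini-batches. The GC
#' feature is standardized with the training-set mean and standard deviation
#' (stored in the model and reused at prediction time).
#'
#' @param encoded Result of [encode_sequences()] with a `label` element, or a
#'   [Biostrings::DNAStringSet] with a `label` metadata column.
#' @param config A [cnn_config()].
#' @return An object of class `enhancer_cnn`: parameters, config, GC scaling
#'   and the per-epoch training loss log.
#' @export
train_enhancer_cnn <- function(encoded, config = cnn_config()) {
  if (methods::is(encoded, "XStringSet"))
    encoded <- encode_sequences(encoded, config$input_length)
  y <- encoded$label
  if (is.null(y)) stop("training requires labelled examples")
  if (length(unique(y)) < 2L)
    stop("constant-label training set rejected")
  if (dim(encoded$onehot)[2L] != config$input_length)
    stop("encoded length ", dim(encoded$onehot)[2L],
         " does not match config input_length ", config$input_length)
  n <- length(y)
  x <- encoded$onehot
  dim(x) <- c(4L * config$input_length, n)
  gc_center <- mean(encoded$gc)
  gc_scale <- stats::sd(encoded$gc)
  if (!is.finite(gc_scale) || gc_scale == 0) gc_scale <- 1
  gcs <- (encoded$gc - gc_center) / gc_scale
  d <- .cnn_dims(config)
  cache <- list(dims = d,
                idx1 = .im2col_idx(4L, config$input_length, config$kernel1),
                idx2 = .im2col_idx(config$filters1, d$g1, config$kernel2))
  set.seed(config$seed)
  par <- .cnn_init(config)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  loss_log <- numeric(config$epochs)
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, n)]
      if (length(bi) < 2L) next
      mask <- NULL
      if (config$dropout > 0) {
        mask <- matrix(stats::rbinom(config$dense_units * length(bi), 1L,
                                     1 - config$dropout) /
                         (1 - config$dropout),
                       config$dense_units, length(bi))
      }
      fw <- .cnn_forward(par, config, x[, bi, drop = FALSE], gcs[bi],
                         cache, mask)
      loss <- .bce(fw$prob, y[bi])
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; lower the learning rate")
      grads <- .cnn_backward(par, config, fw, y[bi], cache, mask)
      t <- t + 1L
      st <- .adam_step(par, grads, state, config$learning_rate, t)
      par <- st$par; state <- st$state
      epoch_loss <- epoch_loss + loss
      nb <- nb + 1L
    }
    loss_log[epoch] <- epoch_loss / nb
  }
  structure(list(par = par, config = config,
                 gc_center = gc_center, gc_scale = gc_scale,
                 loss_log = loss_log),
            class = "enhancer_cnn")
}

#' @export
print.enhancer_cnn <- function(x, ...) {
  cat("enhancer_cnn: L =", x$config$input_length,
      "| conv", x$config$filters1, "x", x$config$kernel1,
      "-> pool", x$config$pool1,
      "| conv", x$config$filters2, "x", x$config$kernel2,
      "-> global max | dense", x$config$dense_units,
      if (x$config$use_gc) "+ GC" else "(no GC)",
      "\n  final training loss:", signif(tail(x$loss_log, 1L), 4), "\n")
  invisible(x)
}

#' Predict enhancer probabilities
#'
#' Deterministic evaluation (no dropout); batched evaluation equals
#' single-example evaluation. Scores are computed on the given strand only.
#'
#' @param object A trained [train_enhancer_cnn()] model.
#' @param newdata Result of [encode_sequences()] (at the model's input
#'   length) or a [Biostrings::DNAStringSet].
#' @param ... Unused.
#' @return Data frame with columns `sequence_id` and `probability`, in input
#'   order.
#' @export
predict.enhancer_cnn <- function(object, newdata, ...) {
  cfg <- object$config
  if (methods::is(newdata, "XStringSet"))
    newdata <- encode_sequences(newdata, cfg$input_length)
  if (dim(newdata$onehot)[2L] != cfg$input_length)
    stop("encoded length ", dim(newdata$onehot)[2L],
         " does not match model input_length ", cfg$input_length)
  n <- dim(newdata$onehot)[3L]
  x <- newdata$onehot
  dim(x) <- c(4L * cfg$input_length, n)
  gcs <- (newdata$gc - object$gc_center) / object$gc_scale
  d <- .cnn_dims(cfg)
  cache <- list(dims = d,
                idx1 = .im2col_idx(4L, cfg$input_length, cfg$kernel1),
                idx2 = .im2col_idx(cfg$filters1, d$g1, cfg$kernel2))
  probs <- numeric(n)
  bs <- max(cfg$batch_size, 64L)
  for (start in seq(1L, n, by = bs)) {
    bi <- start:min(start + bs - 1L, n)
    fw <- .cnn_forward(object$par, cfg, x[, bi, drop = FALSE], gcs[bi],
                       cache, NULL)
    probs[bi] <- fw$prob
  }
  data.frame(sequence_id = newdata$ids, probability = probs,
             stringsAsFactors = FALSE)
}

#' Bin probability scores into enhancer classes
#'
#' `probability >= strong_threshold` is `"strong"`,
#' `weak_threshold <= probability < strong_threshold` is `"weak"`, anything
#' below is `"non"`; thresholds are inclusive at the lower edge of each
#' class, so the three classes partition every scored sequence.
#'
#' @param scores Data frame from [predict.enhancer_cnn()] (columns
#'   `sequence_id`, `probability`) or a numeric vector.
#' @param strong_threshold,weak_threshold Cut-points (defaults 0.8 / 0.5).
#' @return The input with an `enhancer_class` column (factor levels
#'   `strong`, `weak`, `non`); for a numeric input, a character vector.
#' @export
classify_enhancers <- function(scores, strong_threshold = 0.8,
                               weak_threshold = 0.5) {
  stopifnot(weak_threshold < strong_threshold)
  p <- if (is.data.frame(scores)) scores$probability else scores
  cls <- ifelse(p >= strong_threshold, "strong",
                ifelse(p >= weak_threshold, "weak", "non"))
  if (is.data.frame(scores)) {
    scores$enhancer_class <- cls
    scores
  } else cls
}
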