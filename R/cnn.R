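# Internal 1D-CNN engine: two convolution blocks (ReLU, max-pool after the
# first, global max-pool after the second), the GC scalar concatenated onto
# the pooled features, one dense ReLU layer and a sigmoid output. Implemented
# as im2col matrix products so training runs on BLAS; all randomness
# (initialisation, shuffling, dropout) flows from a single seed.

.cnn_dims <- function(cfg) {
  L <- cfg$input_length
  p1 <- L - cfg$kernel1 + 1L                 # conv1 positions
  g1 <- p1 %/% cfg$pool1                     # pooled positions
  p2 <- g1 - cfg$kernel2 + 1L                # conv2 positions
  if (p2 < 1L) stop("input_length too small for this architecture")
  list(L = L, p1 = p1, g1 = g1, p2 = p2,
       k1 = 4L * cfg$kernel1, k2 = cfg$filters1 * cfg$kernel2)
}

# im2col index vector for channel-major flattened input:
# element (channel, position) lives at (position-1)*n_chan + channel, so a
# window of `kernel` positions is a contiguous run of kernel*n_chan entries.
.im2col_idx <- function(n_chan, n_pos, kernel) {
  starts <- (seq_len(n_pos - kernel + 1L) - 1L) * n_chan
  as.vector(outer(seq_len(kernel * n_chan), starts, "+"))
}

.he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

.cnn_init <- function(cfg) {
  d <- .cnn_dims(cfg)
  list(W1 = .he_init(cfg$filters1, d$k1), b1 = numeric(cfg$filters1),
       W2 = .he_init(cfg$filters2, d$k2), b2 = numeric(cfg$filters2),
       Wd = .he_init(cfg$dense_units, cfg$filters2 + as.integer(cfg$use_gc)),
       bd = numeric(cfg$dense_units),
       Wo = .he_init(1L, cfg$dense_units), bo = 0)
}

# Forward pass over a batch. x: (4*L) x B channel-major one-hot; gc: length-B
# standardized GC. Returns activations needed for backprop when train=TRUE.
.cnn_forward <- function(par, cfg, x, gc, cache, dropout_mask = NULL) {
  d <- cache$dims
  B <- ncol(x)
  # conv block 1
  C1 <- x[cache$idx1, , drop = FALSE]
  dim(C1) <- c(d$k1, d$p1 * B)
  Z1 <- par$W1 %*% C1 + par$b1
  A1 <- Z1 * (Z1 > 0)
  # max-pool width pool1 (truncating tail positions)
  keep <- d$g1 * cfg$pool1
  A1a <- A1
  dim(A1a) <- c(cfg$filters1, d$p1, B)
  A1a <- A1a[, seq_len(keep), , drop = FALSE]
  dim(A1a) <- c(cfg$filters1, cfg$pool1, d$g1, B)
  P <- A1a[, 1L, , , drop = FALSE]
  dim(P) <- c(cfg$filters1, d$g1, B)
  amax1 <- array(1L, dim(P))
  for (q in 2L:cfg$pool1) {
    cand <- A1a[, q, , , drop = FALSE]
    dim(cand) <- dim(P)
    upd <- cand > P
    P[upd] <- cand[upd]
    amax1[upd] <- q
  }
  # conv block 2 on pooled features
  Pf <- P
  dim(Pf) <- c(cfg$filters1 * d$g1, B)
  C2 <- Pf[cache$idx2, , drop = FALSE]
  dim(C2) <- c(d$k2, d$p2 * B)
  Z2 <- par$W2 %*% C2 + par$b2
  A2 <- Z2 * (Z2 > 0)
  # global max-pool over positions
  A2a <- A2
  dim(A2a) <- c(cfg$filters2, d$p2, B)
  T2 <- aperm(A2a, c(1L, 3L, 2L))
  dim(T2) <- c(cfg$filters2 * B, d$p2)
  amax2 <- max.col(T2, ties.method = "first")
  gfeat <- T2[cbind(seq_len(nrow(T2)), amax2)]
  dim(gfeat) <- c(cfg$filters2, B)
  h <- if (cfg$use_gc) rbind(gfeat, gc) else gfeat
  Zd <- par$Wd %*% h + par$bd
  Ad <- Zd * (Zd > 0)
  if (!is.null(dropout_mask)) Ad <- Ad * dropout_mask
  Zo <- as.numeric(par$Wo %*% Ad + par$bo)
  prob <- 1 / (1 + exp(-Zo))
  list(prob = prob, C1 = C1, Z1 = Z1, amax1 = amax1, C2 = C2, Z2 = Z2,
       amax2 = amax2, h = h, Zd = Zd, Ad = Ad, B = B)
}

.cnn_backward <- function(par, cfg, fw, y, cache, dropout_mask = NULL) {
  d <- cache$dims
  B <- fw$B
  dZo <- matrix((fw$prob - y) / B, nrow = 1L)
  g <- list()
  g$Wo <- dZo %*% t(fw$Ad)
  g$bo <- sum(dZo)
  dAd <- t(par$Wo) %*% dZo
  if (!is.null(dropout_mask)) dAd <- dAd * dropout_mask
  dZd <- dAd * (fw$Zd > 0)
  g$Wd <- dZd %*% t(fw$h)
  g$bd <- rowSums(dZd)
  dh <- t(par$Wd) %*% dZd
  dg <- dh[seq_len(cfg$filters2), , drop = FALSE]
  # scatter through the global max-pool
  dA2 <- numeric(cfg$filters2 * d$p2 * B)
  fi <- rep(seq_len(cfg$filters2), times = B)
  ei <- rep(seq_len(B), each = cfg$filters2)
  li <- fi + cfg$filters2 * ((fw$amax2 - 1L) + d$p2 * (ei - 1L))
  dA2[li] <- as.numeric(dg)
  dim(dA2) <- c(cfg$filters2, d$p2 * B)
  dZ2 <- dA2 * (fw$Z2 > 0)
  g$W2 <- dZ2 %*% t(fw$C2)
  g$b2 <- rowSums(dZ2)
  dC2 <- t(par$W2) %*% dZ2
  # gather-add back through im2col2 onto the pooled feature map
  dim(dC2) <- c(d$k2 * d$p2, B)
  dPf <- rowsum(dC2, group = cache$idx2, reorder = TRUE)
  # rowsum keeps only groups present; idx2 covers 1..filters1*g1 densely
  dP <- matrix(0, cfg$filters1 * d$g1, B)
  dP[as.integer(rownames(dPf)), ] <- dPf
  # scatter through max-pool 1
  dA1 <- numeric(cfg$filters1 * d$p1 * B)
  fi1 <- rep(seq_len(cfg$filters1), times = d$g1 * B)
  gi1 <- rep(rep(seq_len(d$g1), each = cfg$filters1), times = B)
  ei1 <- rep(seq_len(B), each = cfg$filters1 * d$g1)
  w1 <- (gi1 - 1L) * cfg$pool1 + as.integer(fw$amax1)
  li1 <- fi1 + cfg$filters1 * ((w1 - 1L) + d$p1 * (ei1 - 1L))
  dA1[li1] <- as.numeric(dP)
  dim(dA1) <- c(cfg$filters1, d$p1 * B)
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$W1 <- dZ1 %*% t(fw$C1)
  g$b1 <- rowSums(dZ1)
  g
}

.adam_step <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
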