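## Internal mini neural-network engine.
##
## Implements exactly what the patch classifier needs: a small convolutional
## backbone, the dense(198)-dense(198)-dropout(0.5)-dense(C) head, softmax
## cross-entropy, Adam, inverted dropout, and vectorised forward/backward
## passes over mini-batches. Written against base R matrix algebra; batches
## are rows, weights are (in x out) matrices.
##
## small_convnet_test architecture (input 99 x 99 grayscale, flattened
## column-major, intensities 0..255):
##   fixed 3x3 block-mean pool          99x99  -> 33x33   (no parameters)
##   conv 5x5, 8 filters, stride 2      33x33  -> 15x15x8 (ReLU)
##   5x5 block-mean pool                15x15  -> 3x3     (per filter, 72 feats)
##   dense 198 (ReLU) -> dense 198 (ReLU) -> dropout 0.5 -> dense C
## The conv + pools form the "backbone" that the two-phase schedule freezes
## and unfreezes; the dense stack is the "head".

CONV_KERNEL <- 5L
CONV_FILTERS <- 8L
CONV_STRIDE <- 2L

## flat column-major index of (row, col) in an n-row grid
flat_idx <- function(row, col, nrow) (col - 1L) * nrow + row

## index matrix for an a x a block-mean pool of an n x n grid (n = a * m):
## out (m^2 x a^2), entry [p, k] = input flat index
pool_index <- function(n, a) {
  m <- n %/% a
  stopifnot(m * a == n)
  out <- matrix(0L, m * m, a * a)
  for (j in seq_len(m)) for (i in seq_len(m)) {
    p <- (j - 1L) * m + i
    k <- 0L
    for (v in seq_len(a)) for (u in seq_len(a)) {
      k <- k + 1L
      out[p, k] <- flat_idx((i - 1L) * a + u, (j - 1L) * a + v, n)
    }
  }
  out
}

## im2col index matrix for a k x k valid convolution with stride s on an
## n x n grid: (n_pos^2 x k^2), [p, kk] = input flat index
conv_index <- function(n, k, s) {
  npos <- (n - k) %/% s + 1L
  out <- matrix(0L, npos * npos, k * k)
  for (j in seq_len(npos)) for (i in seq_len(npos)) {
    p <- (j - 1L) * npos + i
    kk <- 0L
    for (v in seq_len(k)) for (u in seq_len(k)) {
      kk <- kk + 1L
      out[p, kk] <- flat_idx((i - 1L) * s + u, (j - 1L) * s + v, n)
    }
  }
  out
}

## mean-pool matrix (n_pos^2 x m^2) mapping conv positions to an m x m grid
## of equal blocks (requires npos = m * a)
pool_matrix <- function(npos, m) {
  a <- npos %/% m
  stopifnot(a * m == npos)
  P <- matrix(0, npos * npos, m * m)
  for (j in seq_len(npos)) for (i in seq_len(npos)) {
    p <- (j - 1L) * npos + i
    bi <- (i - 1L) %/% a + 1L
    bj <- (j - 1L) %/% a + 1L
    P[p, (bj - 1L) * m + bi] <- 1 / (a * a)
  }
  P
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

## Apply the fixed 3x3 mean pool (and 0..255 -> 0..1 scaling) to a batch of
## flattened 99x99 patches. Done once per dataset, not per batch.
nn_preprocess <- function(model, X) {
  stopifnot(ncol(X) == model$input_size^2)
  idx <- model$idx$pool1
  Xp <- matrix(0, nrow(X), nrow(idx))
  for (k in seq_len(ncol(idx))) Xp <- Xp + X[, idx[, k], drop = FALSE]
  Xp / (ncol(idx) * 255)
}

## Forward pass on preprocessed input Xp (B x 33^2). Returns logits and,
## when keep_cache, the intermediates needed for the backward pass.
nn_forward <- function(model, Xp, training = FALSE, keep_cache = FALSE) {
  p <- model$params
  B <- nrow(Xp)
  npos2 <- nrow(model$idx$conv)
  G <- Xp[, as.vector(model$idx$conv), drop = FALSE]
  dim(G) <- c(B * npos2, ncol(model$idx$conv))
  Zc <- G %*% p$Wc
  Zc <- sweep(Zc, 2L, p$bc, "+")
  Ac <- pmax(Zc, 0)
  F <- ncol(p$Wc)
  m2 <- ncol(model$idx$pool2)
  H0 <- matrix(0, B, m2 * F)
  dim(Ac) <- c(B, npos2, F)
  for (f in seq_len(F)) {
    H0[, (f - 1L) * m2 + seq_len(m2)] <- Ac[, , f] %*% model$idx$pool2
  }
  Z1 <- sweep(H0 %*% p$W1, 2L, p$b1, "+"); H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% p$W2, 2L, p$b2, "+"); H2 <- pmax(Z2, 0)
  if (training && model$cfg$dropout_rate > 0) {
    keep <- 1 - model$cfg$dropout_rate
    mask <- matrix(stats::rbinom(length(H2), 1L, keep) / keep,
                   nrow(H2), ncol(H2))
    D <- H2 * mask
  } else {
    mask <- NULL
    D <- H2
  }
  logits <- sweep(D %*% p$W3, 2L, p$b3, "+")
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, G = G, Zc = Zc, H0 = H0, Z1 = Z1, H1 = H1,
       Z2 = Z2, H2 = H2, mask = mask, D = D, B = B)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

## mean categorical cross-entropy of integer codes y (0-based) under logits
nn_loss <- function(logits, y) {
  pr <- softmax_rows(logits)
  -mean(log(pmax(pr[cbind(seq_len(nrow(pr)), y + 1L)], 1e-12)))
}

## gradients of the mean cross-entropy; conv gradients only when !frozen
nn_backward <- function(model, cache, y, frozen) {
  p <- model$params
  B <- cache$B
  pr <- softmax_rows(cache$logits)
  pr[cbind(seq_len(B), y + 1L)] <- pr[cbind(seq_len(B), y + 1L)] - 1
  dlogits <- pr / B
  g <- list()
  g$W3 <- crossprod(cache$D, dlogits); g$b3 <- colSums(dlogits)
  dD <- tcrossprod(dlogits, p$W3)
  dH2 <- if (is.null(cache$mask)) dD else dD * cache$mask
  dZ2 <- dH2 * (cache$Z2 > 0)
  g$W2 <- crossprod(cache$H1, dZ2); g$b2 <- colSums(dZ2)
  dZ1 <- tcrossprod(dZ2, p$W2) * (cache$Z1 > 0)
  g$W1 <- crossprod(cache$H0, dZ1); g$b1 <- colSums(dZ1)
  if (!frozen) {
    dH0 <- tcrossprod(dZ1, p$W1)
    F <- ncol(p$Wc)
    npos2 <- nrow(model$idx$conv)
    m2 <- ncol(model$idx$pool2)
    dAc <- array(0, c(B, npos2, F))
    for (f in seq_len(F)) {
      dAc[, , f] <- tcrossprod(dH0[, (f - 1L) * m2 + seq_len(m2), drop = FALSE],
                               model$idx$pool2)
    }
    dim(dAc) <- c(B * npos2, F)
    dZc <- dAc * (cache$Zc > 0)
    g$Wc <- crossprod(cache$G, dZc); g$bc <- colSums(dZc)
  }
  g
}

adam_state <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## macro-F1 over classes with support (0-based codes)
macro_f1 <- function(truth, pred, n_classes) {
  f1s <- c()
  for (cl in 0:(n_classes - 1L)) {
    support <- sum(truth == cl)
    if (support == 0L) next
    tp <- sum(truth == cl & pred == cl)
    prec <- if (sum(pred == cl) > 0L) tp / sum(pred == cl) else 0
    rec <- tp / support
    f1s <- c(f1s, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  if (length(f1s)) mean(f1s) else NA_real_
}
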