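# Minimal neural-network engine with hand-derived backpropagation.
#
# The classifier scaffold needs a small convolutional stack, an optional
# 2-token attention encoder for image/time fusion, weighted cross-entropy
# and Adam. No deep-learning runtime is assumed: all layers are implemented
# directly on base-R arrays (column-major, images as H x W x C) and every
# backward pass is verified against finite differences in the test suite.

# ---- RNG scoping -----------------------------------------------------------

# run code under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- im2col convolution (3x3, stride 1, pad 1) -----------------------------

# precompute gather indices mapping a zero-padded (H+2, W+2, C) array to the
# (9C x HW) column matrix of 3x3 patches
im2col_indices <- function(H, W, C, k = 3L, pad = 1L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  di <- rep(0:(k - 1L), times = k)
  dj <- rep(0:(k - 1L), each = k)
  lin <- outer(di, oi, "+") + Hp * (outer(dj, oj, "+") - 1L)  # k^2 x HW
  idx <- vapply(seq_len(C), function(ch) lin + Hp * Wp * (ch - 1L),
                matrix(0L, nrow = k * k, ncol = H * W))
  idx <- matrix(aperm(idx, c(1, 3, 2)), nrow = k * k * C)     # rows: offset within channel, channel-major blocks
  list(idx = idx, H = H, W = W, C = C, Hp = Hp, Wp = Wp, pad = pad, k = k)
}

pad_image <- function(x, ii) {
  xp <- array(0, c(ii$Hp, ii$Wp, ii$C))
  xp[ii$pad + seq_len(ii$H), ii$pad + seq_len(ii$W), ] <- x
  xp
}

conv_forward <- function(x, Wc, b, ii) {
  xp <- pad_image(x, ii)
  Xc <- matrix(xp[ii$idx], nrow = nrow(ii$idx))       # 9C x HW
  out <- Wc %*% Xc + b                                # Cout x HW
  y <- array(t(out), c(ii$H, ii$W, nrow(Wc)))
  list(y = y, Xc = Xc)
}

conv_backward <- function(dY, Wc, cache, ii) {
  Cout <- nrow(Wc)
  dYm <- t(matrix(dY, ncol = Cout))                   # Cout x HW
  dW <- dYm %*% t(cache$Xc)
  db <- rowSums(dYm)
  dXc <- crossprod(Wc, dYm)                           # 9C x HW
  acc <- rowsum(as.vector(dXc), group = as.vector(ii$idx))
  dxp <- numeric(ii$Hp * ii$Wp * ii$C)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, c(ii$Hp, ii$Wp, ii$C))
  dx <- dxp[ii$pad + seq_len(ii$H), ii$pad + seq_len(ii$W), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# ---- 2x2 max pooling -------------------------------------------------------

maxpool_forward <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  x4 <- array(x, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  xr <- aperm(x4, c(2, 4, 5, 1, 3))                   # (H/2, W/2, C, 2, 2)
  xm <- matrix(xr, ncol = 4L)
  am <- max.col(xm, ties.method = "first")
  y <- array(xm[cbind(seq_len(nrow(xm)), am)], c(H %/% 2L, W %/% 2L, C))
  list(y = y, am = am, dims = d)
}

maxpool_backward <- function(dY, cache) {
  d <- cache$dims
  n <- length(dY)
  dxm <- matrix(0, nrow = n, ncol = 4L)
  dxm[cbind(seq_len(n), cache$am)] <- as.vector(dY)
  dx4 <- aperm(array(dxm, c(d[1] %/% 2L, d[2] %/% 2L, d[3], 2L, 2L)),
               c(4, 1, 5, 2, 3))
  array(dx4, d)
}

# ---- attention encoder layer (2 tokens) ------------------------------------

# single encoder layer: multi-head self-attention with residual, then a
# position-wise feed-forward block with residual (no layer norm at this
# scale; the fusion path is tiny and trains stably without it)
encoder_forward <- function(Tm, p, n_heads) {
  H <- ncol(Tm)
  dh <- H %/% n_heads
  Q <- Tm %*% p$Wq; K <- Tm %*% p$Wk; V <- Tm %*% p$Wv
  A_list <- vector("list", n_heads)
  O <- matrix(0, nrow(Tm), H)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  Att <- O %*% p$Wo
  T1 <- Tm + Att
  pre <- sweep(T1 %*% p$W1, 2, p$b1, "+")
  Hf <- pmax(pre, 0)
  T2 <- T1 + sweep(Hf %*% p$W2, 2, p$b2, "+")
  list(T2 = T2, cache = list(Tm = Tm, Q = Q, K = K, V = V, A = A_list,
                             O = O, T1 = T1, pre = pre, Hf = Hf))
}

encoder_backward <- function(dT2, p, cache, n_heads) {
  H <- ncol(cache$Tm)
  dh <- H %/% n_heads
  g <- list()
  g$b2 <- colSums(dT2)
  g$W2 <- crossprod(cache$Hf, dT2)
  dHf <- tcrossprod(dT2, p$W2) * (cache$pre > 0)
  g$b1 <- colSums(dHf)
  g$W1 <- crossprod(cache$T1, dHf)
  dT1 <- dT2 + tcrossprod(dHf, p$W1)
  dAtt <- dT1
  g$Wo <- crossprod(cache$O, dAtt)
  dO <- tcrossprod(dAtt, p$Wo)
  dQ <- matrix(0, nrow(dT2), H); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$Wq <- crossprod(cache$Tm, dQ)
  g$Wk <- crossprod(cache$Tm, dK)
  g$Wv <- crossprod(cache$Tm, dV)
  dTm <- dT1 + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
    tcrossprod(dV, p$Wv)
  list(grads = g, dTm = dTm)
}

# ---- weighted cross-entropy ------------------------------------------------

log_softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  z0 <- z - m
  z0 - log(rowSums(exp(z0)))
}

# weighted CE with per-target weights; reduction divides by the summed
# weights of the targets in the batch (so unit weights give the plain mean)
weighted_ce <- function(logits, target, weights) {
  n <- nrow(logits)
  w <- weights[target]
  ls <- log_softmax_rows(logits)
  loss <- -sum(w * ls[cbind(seq_len(n), target)]) / sum(w)
  p <- exp(ls)
  grad <- p
  grad[cbind(seq_len(n), target)] <- grad[cbind(seq_len(n), target)] - 1
  grad <- grad * (w / sum(w))
  list(loss = loss, grad = grad)
}

#' Two-head classification loss
#'
#' Sum of the class-weighted cross-entropy losses of the two classifier
#' heads of the fused model (a single head may be passed as both arguments
#' divided by two, but the canonical use is one loss per head). Weighting
#' follows the inverse-class-frequency convention of
#' [inverse_class_frequency_weights()]; the reduction divides by the summed
#' target weights so that unit weights recover the plain per-sample mean.
#'
#' @param logits_head1,logits_head2 numeric matrices (samples x classes) of
#'   unnormalised scores. Pass `NULL` for `logits_head2` with a
#'   single-head model.
#' @param target integer vector of 1-based true class indices.
#' @param class_weights per-class weight vector (default all 1).
#' @return single non-negative number; zero only in the limit of both heads
#'   being certain and correct.
#' @examples
#' z <- matrix(0, 2, 4)  # uniform over 4 classes
#' combined_loss(z, z, c(1L, 2L))  # 2 * log(4)
#' @export
combined_loss <- function(logits_head1, logits_head2, target,
                          class_weights = NULL) {
  logits_head1 <- as.matrix(logits_head1)
  if (is.null(class_weights)) class_weights <- rep(1, ncol(logits_head1))
  if (length(class_weights) != ncol(logits_head1)) {
    stop("class_weights length must match the number of classes",
         call. = FALSE)
  }
  target <- as.integer(target)
  if (any(target < 1L | target > ncol(logits_head1))) {
    stop("target indices out of range", call. = FALSE)
  }
  l1 <- weighted_ce(logits_head1, target, class_weights)$loss
  if (is.null(logits_head2)) return(l1)
  logits_head2 <- as.matrix(logits_head2)
  if (!all(dim(logits_head2) == dim(logits_head1))) {
    stop("the two logit matrices must have identical shape", call. = FALSE)
  }
  l1 + weighted_ce(logits_head2, target, class_weights)$loss
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
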