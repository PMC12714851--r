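#' Causal temporal convolution
#'
#' Depthwise causal convolution along time: for every feature `f`,
#' \deqn{Y[t, f] = \sum_{k=1}^{K} X[t - k, f] \, W[k, f] + b[f]}
#' The current sample is excluded (the kernel index starts at 1), and the left
#' boundary is zero-padded so the output length equals the input length.
#'
#' @param X Numeric matrix `time x features`.
#' @param W Kernel matrix `K x features` (a length-`K` vector is recycled
#'   across features).
#' @param b Bias, one per feature (scalar recycled).
#' @return Matrix of the same shape as `X`.
#' @export
temporal_conv <- function(X, W, b = 0) {
  X <- as.matrix(X)
  Tn <- nrow(X); Fn <- ncol(X)
  if (is.null(dim(W))) W <- matrix(W, ncol = Fn, nrow = length(W))
  if (ncol(W) == 1L && Fn > 1L) W <- W[, rep(1L, Fn), drop = FALSE]
  if (ncol(W) != Fn) stop("kernel/feature mismatch: ", ncol(W), " vs ", Fn)
  K <- nrow(W)
  b <- rep_len(b, Fn)
  Y <- matrix(rep(b, each = Tn), Tn, Fn)
  for (k in seq_len(K)) {
    if (k < Tn) {
      Y[(k + 1L):Tn, ] <- Y[(k + 1L):Tn, ] +
        sweep(X[1:(Tn - k), , drop = FALSE], 2L, W[k, ], "*")
    }
  }
  Y
}

temporal_conv_backward <- function(dY, X, W) {
  Tn <- nrow(X); Fn <- ncol(X); K <- nrow(W)
  dX <- matrix(0, Tn, Fn)
  dW <- matrix(0, K, Fn)
  for (k in seq_len(K)) {
    if (k < Tn) {
      hi <- (k + 1L):Tn; lo <- 1:(Tn - k)
      dX[lo, ] <- dX[lo, ] + sweep(dY[hi, , drop = FALSE], 2L, W[k, ], "*")
      dW[k, ] <- colSums(dY[hi, , drop = FALSE] * X[lo, , drop = FALSE])
    }
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

#' Temporal shift
#'
#' Parameter-free temporal mixing: the first `floor(fraction * features)`
#' feature columns are delayed one step, the next block advanced one step,
#' and the remainder left unchanged; vacated positions are zero-filled.
#'
#' @param X Numeric matrix `time x features`.
#' @param shift_fraction Fraction of features shifted in each direction
#'   (in `[0, 0.5]`).
#' @return Matrix of the same shape as `X`.
#' @export
temporal_shift <- function(X, shift_fraction) {
  stopifnot(shift_fraction >= 0, shift_fraction <= 0.5)
  X <- as.matrix(X)
  Tn <- nrow(X); Fn <- ncol(X)
  m <- floor(shift_fraction * Fn)
  if (m == 0L || Tn < 2L) return(X)
  Y <- X
  fwd <- seq_len(m); bwd <- m + seq_len(m)
  Y[2:Tn, fwd] <- X[1:(Tn - 1L), fwd, drop = FALSE]
  Y[1L, fwd] <- 0
  Y[1:(Tn - 1L), bwd] <- X[2:Tn, bwd, drop = FALSE]
  Y[Tn, bwd] <- 0
  Y
}

temporal_shift_backward <- function(dY, shift_fraction) {
  Tn <- nrow(dY); Fn <- ncol(dY)
  m <- floor(shift_fraction * Fn)
  if (m == 0L || Tn < 2L) return(dY)
  dX <- dY
  fwd <- seq_len(m); bwd <- m + seq_len(m)
  dX[1:(Tn - 1L), fwd] <- dY[2:Tn, fwd, drop = FALSE]
  dX[Tn, fwd] <- 0
  dX[2:Tn, bwd] <- dY[1:(Tn - 1L), bwd, drop = FALSE]
  dX[1L, bwd] <- 0
  dX
}

#' Sinusoidal positional encoding
#'
#' \deqn{PE(pos, 2i) = \sin(pos / 10000^{2i/d}), \quad
#'       PE(pos, 2i+1) = \cos(pos / 10000^{2i/d})}
#' with `pos` starting at 0. The matrix is added to the input embedding so the
#' model can recover sequence order without recurrence.
#'
#' @param length Sequence length (rows).
#' @param d Encoding width (must be even).
#' @return Matrix `length x d`.
#' @export
positional_encoding <- function(length, d) {
  if (d %% 2L != 0L) stop("positional encoding width d must be even")
  pos <- 0:(length - 1L)
  i <- 0:(d / 2L - 1L)
  ang <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, length, d)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

#' Multi-head scaled dot-product attention
#'
#' Queries, keys and values are linearly projected, split column-wise into
#' `h` heads, attended independently with
#' `softmax(Q' K'^T / sqrt(d_k)) V'`, concatenated, and reprojected by `W_O`.
#'
#' @param Q,K_in,V Numeric matrices `time x d` (self-attention passes the same
#'   matrix for all three).
#' @param params List with projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (each `d x d`).
#' @param h Number of heads; `d` must be divisible by `h`.
#' @return Matrix `time x d`.
#' @export
multi_head_attention <- function(Q, K_in, V, params, h) {
  mha_forward(Q, K_in, V, params, h)$Y
}

mha_forward <- function(Q, K_in, V, params, h) {
  d <- ncol(Q)
  if (d %% h != 0L) stop("width ", d, " not divisible by n_heads ", h)
  dk <- d %/% h
  Qp <- Q %*% params$Wq; Kp <- K_in %*% params$Wk; Vp <- V %*% params$Wv
  Tn <- nrow(Q)
  O <- matrix(0, Tn, d)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    S <- Qp[, cols, drop = FALSE] %*% t(Kp[, cols, drop = FALSE]) / sqrt(dk)
    A[[i]] <- softmax_rows(S)
    O[, cols] <- A[[i]] %*% Vp[, cols, drop = FALSE]
  }
  list(Y = O %*% params$Wo, O = O, A = A, Qp = Qp, Kp = Kp, Vp = Vp)
}

# self-attention backward: Q = K_in = V = X
mha_backward <- function(dY, X, cache, params, h) {
  d <- ncol(X); dk <- d %/% h
  dWo <- t(cache$O) %*% dY
  dO <- dY %*% t(params$Wo)
  dQp <- matrix(0, nrow(X), d); dKp <- dQp; dVp <- dQp
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    Ai <- cache$A[[i]]
    dOi <- dO[, cols, drop = FALSE]
    Vi <- cache$Vp[, cols, drop = FALSE]
    dA <- dOi %*% t(Vi)
    dVp[, cols] <- t(Ai) %*% dOi
    dS <- Ai * (dA - rowSums(dA * Ai))
    dQp[, cols] <- dS %*% cache$Kp[, cols, drop = FALSE] / sqrt(dk)
    dKp[, cols] <- t(dS) %*% cache$Qp[, cols, drop = FALSE] / sqrt(dk)
  }
  list(dX = dQp %*% t(params$Wq) + dKp %*% t(params$Wk) + dVp %*% t(params$Wv),
       dWq = t(X) %*% dQp, dWk = t(X) %*% dKp, dWv = t(X) %*% dVp,
       dWo = dWo)
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = max(0, x W1 + b1) W2 + b2`, applied identically at every time
#' position (every row of `x`).
#'
#' @param x Numeric matrix `time x d`.
#' @param params List with `W1` (`d x hidden`), `b1`, `W2` (`hidden x d`),
#'   `b2`.
#' @return Matrix `time x d`.
#' @export
ffn <- function(x, params) {
  ffn_forward(x, params)$Y
}

ffn_forward <- function(x, params, dropout = 0) {
  Z <- sweep(x %*% params$W1, 2L, params$b1, "+")
  H <- pmax(Z, 0)
  mask <- NULL
  if (dropout > 0) {
    mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) /
      (1 - dropout)
    H <- H * mask
  }
  list(Y = sweep(H %*% params$W2, 2L, params$b2, "+"), Z = Z, H = H,
       mask = mask)
}

ffn_backward <- function(dY, x, cache, params) {
  dW2 <- t(cache$H) %*% dY
  db2 <- colSums(dY)
  dH <- dY %*% t(params$W2)
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  dZ <- dH * (cache$Z > 0)
  list(dX = dZ %*% t(params$W1),
       dW1 = t(x) %*% dZ, db1 = colSums(dZ), dW2 = dW2, db2 = db2)
}

# ---- layer normalization ----------------------------------------------------

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(Y = sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+"),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, gamma, "*")
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  mu1 <- rowMeans(dxhat)
  mu2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - mu1 - xhat * mu2) * cache$inv
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}
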