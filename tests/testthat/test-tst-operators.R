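# brute-force oracles, kept deliberately naive and separate from the
# implementations they check

conv_oracle <- function(X, W, b) {
  Tn <- nrow(X); Fn <- ncol(X); K <- nrow(W)
  Y <- matrix(0, Tn, Fn)
  for (t in seq_len(Tn)) {
    for (f in seq_len(Fn)) {
      acc <- b[f]
      for (k in seq_len(K)) {
        if (t - k >= 1) acc <- acc + X[t - k, f] * W[k, f]
      }
      Y[t, f] <- acc
    }
  }
  Y
}

attention_oracle <- function(Q, K_in, V, params, h) {
  d <- ncol(Q); dk <- d / h
  Qp <- Q %*% params$Wq; Kp <- K_in %*% params$Wk; Vp <- V %*% params$Wv
  O <- NULL
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    S <- Qp[, cols, drop = FALSE] %*% t(Kp[, cols, drop = FALSE]) / sqrt(dk)
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    if (nrow(S) == 1) A <- matrix(A, 1)
    O <- cbind(O, A %*% Vp[, cols, drop = FALSE])
  }
  O %*% params$Wo
}

ffn_oracle <- function(x, params) {
  Tn <- nrow(x)
  out <- matrix(0, Tn, ncol(params$W2))
  for (t in seq_len(Tn)) {
    hline <- pmax(as.numeric(x[t, ] %*% params$W1) + params$b1, 0)
    out[t, ] <- as.numeric(hline %*% params$W2) + params$b2
  }
  out
}

test_that("temporal_conv spec examples", {
  # K=1, W=1, b=0: one-step delay with zero head
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(temporal_conv(X, matrix(1, 1, 1), 0),
               matrix(c(0, 1, 2, 3), 4, 1))
  # bias-only
  expect_equal(temporal_conv(X, matrix(0, 3, 1), 0.5),
               matrix(0.5, 4, 1))
  # worked K=2 example
  expect_equal(temporal_conv(X, matrix(c(1, -1), 2, 1), 0),
               matrix(c(0, 1, 1, 1), 4, 1))
  expect_error(temporal_conv(matrix(1, 4, 2), matrix(1, 2, 3)), "mismatch")
})

test_that("temporal_conv matches the brute-force oracle on random shapes", {
  set.seed(71)
  for (i in 1:100) {
    Tn <- sample(2:12, 1); Fn <- sample(1:5, 1); K <- sample(1:6, 1)
    X <- matrix(rnorm(Tn * Fn), Tn, Fn)
    W <- matrix(rnorm(K * Fn), K, Fn)
    b <- rnorm(Fn)
    expect_lt(max(abs(temporal_conv(X, W, b) - conv_oracle(X, W, b))), 1e-9)
  }
})

test_that("temporal_shift index bookkeeping and shape contract", {
  X <- matrix(as.numeric(1:16), 4, 4)   # 4 time steps x 4 features
  expect_identical(temporal_shift(X, 0), X)
  Y <- temporal_shift(X, 0.25)
  expect_equal(dim(Y), dim(X))
  expect_equal(Y[, 1], c(0, 1, 2, 3))       # delayed
  expect_equal(Y[, 2], c(6, 7, 8, 0))       # advanced
  expect_equal(Y[, 3:4], X[, 3:4])          # untouched
  set.seed(72)
  for (i in 1:20) {
    Xi <- matrix(rnorm(60), 10, 6)
    fr <- runif(1, 0, 0.5)
    expect_equal(dim(temporal_shift(Xi, fr)), dim(Xi))
  }
})

test_that("opposite shifts are inverse away from the boundary", {
  set.seed(73)
  X <- matrix(rnorm(80), 10, 8)
  Y <- temporal_shift(X, 0.25)
  m <- floor(0.25 * 8)
  # delayed block recovers when advanced and vice versa, interior rows only
  Z <- Y
  Z[, 1:m] <- rbind(Y[-1, 1:m, drop = FALSE], 0)
  Z[, (m + 1):(2 * m)] <- rbind(0, Y[-10, (m + 1):(2 * m), drop = FALSE])
  expect_equal(Z[2:9, ], X[2:9, ])
})

test_that("positional_encoding values, range and direct evaluation", {
  pe <- positional_encoding(8, 4)
  expect_equal(pe[1, ], c(0, 1, 0, 1))            # pos = 0
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[4, 1], sin(3))                  # PE(3, 0), d = 4
  expect_equal(pe[4, 3], sin(3 / 10000^(2 / 4)))  # PE(3, 2)
  expect_equal(pe[4, 4], cos(3 / 10000^(2 / 4)))
  expect_error(positional_encoding(5, 3), "even")
})

test_that("multi_head_attention degenerate cases", {
  d <- 2
  id <- diag(d)
  params <- list(Wq = id, Wk = id, Wv = id, Wo = id)
  # all keys identical -> uniform softmax -> mean of value rows
  Q <- matrix(rnorm(6), 3, d)
  K_in <- matrix(rep(c(1, 2), each = 3), 3, d)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, d)
  out <- multi_head_attention(Q, K_in, V, params, 1)
  for (r in 1:3) expect_equal(out[r, ], colMeans(V), ignore_attr = TRUE)
  expect_error(multi_head_attention(Q, K_in, V, params, 3), "divisible")
})

test_that("multi_head_attention matches the explicit oracle on random cases", {
  set.seed(74)
  for (i in 1:100) {
    h <- sample(1:3, 1)
    dk <- sample(1:3, 1)
    d <- h * dk
    Tn <- sample(2:6, 1)
    params <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
                   Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d))
    Q <- matrix(rnorm(Tn * d), Tn); K_in <- matrix(rnorm(Tn * d), Tn)
    V <- matrix(rnorm(Tn * d), Tn)
    expect_lt(max(abs(multi_head_attention(Q, K_in, V, params, h) -
                        attention_oracle(Q, K_in, V, params, h))), 1e-9)
  }
})

test_that("ffn degenerate cases and random oracle agreement", {
  # ReLU kills the first term -> output is b2 broadcast
  p <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(3, -1))
  x <- matrix(c(-1, -2, -3, -4), 2, 2)
  expect_equal(ffn(x, p), matrix(rep(c(3, -1), each = 2), 2, 2))
  # identity composition on nonnegative input
  xp <- matrix(c(1, 2, 3, 4), 2, 2)
  p0 <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  expect_equal(ffn(xp, p0), xp)
  set.seed(75)
  for (i in 1:100) {
    d_in <- sample(2:5, 1); hdim <- sample(1:6, 1); d_out <- sample(2:5, 1)
    Tn <- sample(1:6, 1)
    pr <- list(W1 = matrix(rnorm(d_in * hdim), d_in),
               b1 = rnorm(hdim),
               W2 = matrix(rnorm(hdim * d_out), hdim),
               b2 = rnorm(d_out))
    xr <- matrix(rnorm(Tn * d_in), Tn)
    expect_lt(max(abs(ffn(xr, pr) - ffn_oracle(xr, pr))), 1e-9)
  }
})
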