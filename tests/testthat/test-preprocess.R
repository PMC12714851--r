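test_that("remove_eog: fixed-beta identity and exact cancellation", {
  set.seed(5)
  eog <- rnorm(500)
  eeg <- matrix(rnorm(2 * 500), 2)
  rec <- make_rec(rbind(eeg, eog), fs = 250,
                  labels = c("C3", "C4", "EOG"), eog_index = 3L)
  out0 <- remove_eog(rec, preprocess_config(beta_mode = "fixed",
                                            beta_value = 0))
  expect_equal(out0$rec$data, eeg, ignore_attr = TRUE)
  expect_equal(out0$rec$channel_labels, c("C3", "C4"))

  rec2 <- make_rec(rbind(0.3 * eog, eog), fs = 250,
                   labels = c("C3", "EOG"), eog_index = 2L)
  out <- remove_eog(rec2, preprocess_config(beta_mode = "fixed",
                                            beta_value = 0.3))
  expect_lt(max(abs(out$rec$data)), 1e-12)
})

test_that("remove_eog least squares matches the normal-equations oracle", {
  set.seed(6)
  n <- 2000
  eog <- rnorm(n, sd = 40)
  s <- sin(2 * pi * 10 * (0:(n - 1)) / 250)
  s <- s - mean(s)
  eog_c <- eog - mean(eog)
  s_perp <- s - sum(s * eog_c) / sum(eog_c^2) * eog_c   # exactly orthogonal
  mixed <- s_perp + 0.25 * eog
  rec <- make_rec(rbind(mixed, eog), fs = 250, labels = c("C3", "EOG"),
                  eog_index = 2L)
  out <- remove_eog(rec, preprocess_config(beta_mode = "least_squares"))
  beta_oracle <- sum((mixed - mean(mixed)) * eog_c) / sum(eog_c^2)
  expect_equal(unname(out$beta["C3"]), beta_oracle, tolerance = 1e-12)
  expect_lt(abs(out$beta["C3"] - 0.25), 0.05)
  expect_lt(abs(stats::cor(out$rec$data[1, ], eog)), 1e-6)
})

test_that("remove_eog error modes", {
  rec <- make_rec(matrix(rnorm(100), 1), fs = 100)
  expect_error(remove_eog(rec, preprocess_config()), "EOG channel")
  flat <- make_rec(rbind(rnorm(100), rep(1, 100)), fs = 100,
                   labels = c("C3", "EOG"), eog_index = 2L)
  expect_error(remove_eog(flat, preprocess_config()), "zero-variance")
})

test_that("standardize matches the two-pass oracle and its invariances", {
  x <- c(3.2, -1.5, 0.4, 7.7, 2.2)
  rec <- make_rec(x, fs = 100)
  out <- standardize(rec, preprocess_config())
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))       # population SD
  expect_equal(out$rec$data[1, ], (x - mu) / sigma, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(out$stats$mu), mu)
  expect_equal(unname(out$stats$sigma), sigma)

  # fixed point: already standardized input unchanged
  z <- out$rec$data[1, ]
  out2 <- standardize(make_rec(z, fs = 100), preprocess_config())
  expect_equal(out2$rec$data[1, ], z, ignore_attr = TRUE, tolerance = 1e-9)

  # affine invariance for a > 0
  out3 <- standardize(make_rec(2.5 * x + 17, fs = 100), preprocess_config())
  expect_equal(out3$rec$data, out$rec$data, tolerance = 1e-9)

  # output moments on random input
  set.seed(11)
  r <- standardize(make_rec(matrix(rnorm(3 * 256, 5, 9), 3), fs = 128),
                   preprocess_config())
  expect_lt(max(abs(rowMeans(r$rec$data))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(r$rec$data^2)) - 1)), 1e-9)
})

test_that("standardize sigma-zero policies", {
  rec <- make_rec(rbind(rep(2, 50), rnorm(50)), fs = 100)
  expect_error(standardize(rec, preprocess_config()), "zero-variance")
  out <- standardize(rec,
                     preprocess_config(sigma_zero_policy = "zero_output"))
  expect_true(all(out$rec$data[1, ] == 0))
})

test_that("bandpass_filter passband, DC rejection and notch", {
  cfg <- preprocess_config(band = c(0.5, 40), notch = 50)
  dc <- bandpass_filter(make_rec(rep(5, 1024), fs = 256), cfg)
  expect_lt(mean(dc$data^2) / 25, 0.01)

  s10 <- sine_rec(10, fs = 256, dur = 4)
  f10 <- bandpass_filter(s10, cfg)
  expect_lt(abs(rms(f10$data[1, ]) / rms(s10$data[1, ]) - 1), 0.05)

  s50 <- sine_rec(50, fs = 256, dur = 4)
  f50 <- bandpass_filter(s50, cfg)
  atten_db <- 10 * log10(mean(s50$data^2) / mean(f50$data^2))
  expect_gte(atten_db, 20)

  expect_error(bandpass_filter(sine_rec(10, fs = 60),
                               preprocess_config(band = c(0.5, 40))),
               "Nyquist")
})

test_that("spatial_filter methods behave per contract", {
  set.seed(3)
  x <- matrix(rnorm(4 * 200), 4)
  rec <- make_rec(x, fs = 100)
  same <- make_rec(matrix(rep(rnorm(200), 4), 4, byrow = TRUE), fs = 100)
  car <- spatial_filter(same, preprocess_config())
  expect_lt(max(abs(car$data)), 1e-12)
  car2 <- spatial_filter(rec, preprocess_config())
  expect_lt(max(abs(colMeans(car2$data))), 1e-9)
  none <- spatial_filter(rec, preprocess_config(spatial_method = "none"))
  expect_identical(none$data, rec$data)
  expect_error(
    spatial_filter(rec, preprocess_config(spatial_method = "laplacian")),
    "positions")
  lap <- spatial_filter(rec, preprocess_config(spatial_method = "laplacian"),
                        positions = cbind(1:4, rep(0, 4)), k = 2L)
  expect_equal(dim(lap$data), dim(rec$data))
})

test_that("segment counts follow the window arithmetic", {
  rec <- make_rec(matrix(rnorm(2 * 1280), 2), fs = 128)   # 10 s
  n_segs <- function(w, h) {
    dim(segment(rec, preprocess_config(window_s = w, hop_s = h))$segments)[1]
  }
  expect_equal(n_segs(2, 2), 5L)
  expect_equal(n_segs(2, 1), 9L)
  expect_warning(s0 <- segment(rec, preprocess_config(window_s = 20,
                                                      hop_s = 2)),
                 "0 segments")
  expect_equal(dim(s0$segments)[1], 0L)
  s <- segment(rec, preprocess_config(window_s = 2, hop_s = 2))
  expect_equal(dim(s$segments)[3], 256L)
  expect_equal(s$segments[2, , 1], rec$data[, 257], ignore_attr = TRUE)
})

test_that("consistency_score is the exact count ratio", {
  expect_equal(consistency_score(rep(TRUE, 5))$consistency_score, 1.0)
  expect_equal(consistency_score(rep(FALSE, 4))$consistency_score, 0.0)
  r <- consistency_score(c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$consistency_score, 0.75)
  expect_equal(r$n_consistent_sessions, 3L)
  expect_error(consistency_score(logical(0)))
  # order invariance
  expect_equal(consistency_score(c(FALSE, TRUE, TRUE, TRUE))$consistency_score,
               0.75)
})

test_that("assess_consistency flags a spectrally deviant session", {
  set.seed(21)
  mk <- function(alpha_amp) {
    t <- (0:2499) / 250
    make_rec(rbind(alpha_amp * sin(2 * pi * 10 * t) + rnorm(2500, sd = .5),
                   alpha_amp * sin(2 * pi * 11 * t) + rnorm(2500, sd = .5)),
             fs = 250)
  }
  recs <- c(lapply(rep(5, 6), mk), list(mk(500)))
  flags <- assess_consistency(recs, z = 3)
  expect_true(all(flags[1:6]))
  expect_false(flags[7])
})

test_that("quality_score applies amplitude and flatline criteria exactly", {
  set.seed(31)
  segs <- array(rnorm(10 * 2 * 100, sd = 10), dim = c(10, 2, 100))
  ss <- segment_set(segs, fs = 100)
  cfg <- preprocess_config(validity_amp_uV = 100)
  expect_equal(quality_score(ss, cfg)$quality_score, 1.0)

  segs2 <- segs
  segs2[4, 1, 50] <- 500                        # one spiking segment
  q <- quality_score(segment_set(segs2, fs = 100), cfg)
  expect_equal(q$quality_score, 0.9)
  expect_false(q$valid[4])

  segs3 <- segs
  segs3[7, 2, ] <- 3.14                         # one flatlined channel
  q3 <- quality_score(segment_set(segs3, fs = 100), cfg)
  expect_false(q3$valid[7])
  expect_equal(q3$n_valid_segments, 9L)

  # order invariance
  perm <- c(5:10, 1:4)
  q4 <- quality_score(segment_set(segs2[perm, , ], fs = 100), cfg)
  expect_equal(q4$quality_score, 0.9)
  expect_error(quality_score(segment_set(array(0, c(0, 2, 10))), cfg),
               "empty")
})

test_that("the chain preserves shape apart from EOG removal", {
  set.seed(41)
  n <- 250 * 10
  data <- rbind(matrix(rnorm(3 * n, sd = 5), 3), rnorm(n, sd = 30))
  rec <- make_rec(data, fs = 250, labels = c("Fp1", "Fp2", "Fpz", "EOG"),
                  eog_index = 4L)
  out <- preprocess_session(rec, preprocess_config(window_s = 2, hop_s = 2),
                            montage = load_montage("wearable3"))
  expect_equal(dim(out$segments$segments), c(5L, 3L, 500L))
  expect_length(out$beta, 3L)
  expect_identical(out$segments$channel_labels, c("Fp1", "Fp2", "Fpz"))
})
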