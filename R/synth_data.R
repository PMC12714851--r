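#' Synthetic EEG dataset configuration
#'
#' The generator emulates multichannel oscillatory EEG: each channel is a sum
#' of band-limited oscillations (delta 1-4, theta 4-8, alpha 8-13, beta 13-30
#' Hz) whose relative powers depend on the class, plus white sensor noise.
#' The default contrast doubles class-1 alpha power relative to class 0, a
#' well-known depression-related EEG motif used here purely as a testable
#' discriminative feature. Ocular contamination with a known mixing
#' coefficient is added separately by [inject_artifacts()].
#'
#' @param n_subjects Subjects per class.
#' @param n_classes Number of classes (labels `0, 1, ...`).
#' @param fs Sampling rate, Hz (within the 128-512 wearable/cap range).
#' @param duration_s Recording length per subject, seconds.
#' @param n_channels 3 (wearable) or 128 (cap); other counts allowed with
#'   generic labels.
#' @param band_power Per-class relative band powers: list of named vectors
#'   `c(delta=, theta=, alpha=, beta=)`, one per class.
#' @param osc_rms_uV Total oscillatory RMS amplitude per channel, microvolts.
#' @param noise_sd White noise SD, microvolts.
#' @param eog_beta EOG mixing coefficient used by [inject_artifacts()].
#' @param eog_rate Blink rate, blinks per minute.
#' @param seed RNG seed; all outputs are pure functions of config + seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L, n_classes = 2L, fs = 250,
                         duration_s = 60, n_channels = 3L,
                         band_power = NULL, osc_rms_uV = 10,
                         noise_sd = 0.5, eog_beta = 0.3, eog_rate = 12,
                         seed = 1L) {
  stopifnot(fs >= 128, fs <= 512, n_classes >= 2L, n_subjects >= 1L,
            duration_s > 0, noise_sd >= 0)
  if (is.null(band_power)) {
    base <- c(delta = 1, theta = 1, alpha = 1, beta = 0.5)
    band_power <- lapply(seq_len(n_classes) - 1L, function(cl) {
      bp <- base
      if (cl >= 1L) bp["alpha"] <- 2 * cl
      bp
    })
  }
  stopifnot(length(band_power) == n_classes,
            all(vapply(band_power, function(b) all(b >= 0), logical(1))))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_classes = as.integer(n_classes), fs = fs,
                 duration_s = duration_s, n_channels = as.integer(n_channels),
                 band_power = band_power, osc_rms_uV = osc_rms_uV,
                 noise_sd = noise_sd, eog_beta = eog_beta,
                 eog_rate = eog_rate, seed = as.integer(seed)),
            class = "synth_config")
}

synth_channel_labels <- function(n_channels) {
  if (n_channels == 3L) c("Fp1", "Fp2", "Fpz")
  else if (n_channels == 128L) load_montage("cap128")$channel_labels
  else paste0("CH", seq_len(n_channels))
}

band_edges <- list(delta = c(1, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 30))

# one channel: sum of narrowband Gaussian processes (band-filtered white
# noise scaled to the requested RMS split) plus white sensor noise
synth_channel <- function(n, fs, band_power, osc_rms_uV, noise_sd) {
  x <- numeric(n)
  wsum <- sum(band_power)
  k <- 0:(n - 1L)
  freqs <- pmin(k, n - k) * fs / n
  for (b in names(band_edges)) {
    w <- band_power[[b]]
    if (is.na(w) || w <= 0) next
    rms_b <- osc_rms_uV * sqrt(w / wsum)
    g <- fft_gain(freqs, band_edges[[b]], NULL, tw = 0.5)
    xb <- Re(stats::fft(stats::fft(stats::rnorm(n)) * g, inverse = TRUE)) / n
    x <- x + xb / sqrt(mean(xb^2)) * rms_b
  }
  x + stats::rnorm(n, sd = noise_sd)
}

#' Generate a labelled synthetic EEG dataset
#'
#' @param cfg A [synth_config()].
#' @return A list: `recordings` (list of [eeg_recording()]s), `labels`
#'   (integer class per recording), `manifest` (seed, parameters, session
#'   ids).
#' @export
generate_eeg_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  labels <- integer(0)
  recordings <- list()
  ch_labels <- synth_channel_labels(cfg$n_channels)
  for (cl in seq_len(cfg$n_classes) - 1L) {
    bp <- cfg$band_power[[cl + 1L]]
    for (s in seq_len(cfg$n_subjects)) {
      gain <- stats::runif(1, 0.9, 1.1)   # subject-level amplitude jitter
      data <- t(vapply(seq_len(cfg$n_channels), function(ch) {
        gain * synth_channel(n, cfg$fs, bp, cfg$osc_rms_uV, cfg$noise_sd)
      }, numeric(n)))
      sid <- sprintf("class%d_subj%02d", cl, s)
      recordings[[sid]] <- eeg_recording(data, cfg$fs, ch_labels,
                                         session_id = sid)
      labels <- c(labels, cl)
    }
  }
  manifest <- list(seed = cfg$seed, fs = cfg$fs,
                   duration_s = cfg$duration_s,
                   n_channels = cfg$n_channels,
                   n_subjects = cfg$n_subjects, n_classes = cfg$n_classes,
                   band_power = cfg$band_power,
                   osc_rms_uV = cfg$osc_rms_uV, noise_sd = cfg$noise_sd,
                   eog_beta = cfg$eog_beta, eog_rate = cfg$eog_rate,
                   session_ids = names(recordings), labels = labels)
  list(recordings = recordings, labels = labels, manifest = manifest)
}

#' Contaminate a recording with a synthetic EOG channel
#'
#' Builds a blink train (300 ms raised-cosine transients, 100 uV peak,
#' Poisson arrivals at `cfg$eog_rate` per minute), adds `beta` times it to
#' every EEG channel, and appends the EOG itself as a labelled channel so
#' regression-based removal can be tested against the exact ground truth.
#'
#' @param rec A clean [eeg_recording()].
#' @param cfg A [synth_config()] (uses `eog_beta`, `eog_rate`).
#' @param seed Optional seed; omit to continue the current RNG stream.
#' @return A list: `contaminated` (recording with EOG channel appended and
#'   `eog_index` set), `clean` (the input), `beta` (the exact coefficient),
#'   `eog` (the blink signal).
#' @export
inject_artifacts <- function(rec, cfg = synth_config(), seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(rec)
  fs <- rec$fs
  blink_len <- round(0.3 * fs)
  template <- 50 * (1 - cos(2 * pi * seq_len(blink_len) / blink_len))
  rate_per_sample <- cfg$eog_rate / 60 / fs
  n_blinks <- stats::rpois(1, rate_per_sample * n)
  eog <- numeric(n)
  if (n_blinks > 0) {
    starts <- sort(sample.int(max(n - blink_len, 1L), n_blinks,
                              replace = TRUE))
    for (s in starts) {
      idx <- s:min(s + blink_len - 1L, n)
      eog[idx] <- eog[idx] + template[seq_along(idx)]
    }
  }
  beta <- cfg$eog_beta
  data <- rbind(rec$data + beta * matrix(eog, n_channels(rec), n,
                                         byrow = TRUE),
                eog)
  contaminated <- eeg_recording(
    data, fs, c(rec$channel_labels, "EOG"),
    eog_index = n_channels(rec) + 1L,
    session_id = rec$session_id, t0 = rec$t0)
  list(contaminated = contaminated, clean = rec, beta = beta, eog = eog)
}

#' Generate a random default-family game with known equilibrium
#'
#' Draws leader/follower parameters guaranteed to give interior best
#' responses over the whole leader interval and an interior leader optimum
#' (the cost weight is placed between the first-order-condition values at the
#' two leader bounds). The reference equilibrium is computed from the
#' first-order condition of the reduced leader objective,
#' \deqn{\sum_i \lambda_1 a_i k_i (p_i/q_i) e^{-k_i (p_i x - r_i)/q_i}
#'       = \lambda_2 \sum_i (e_i p_i / q_i + g_i),}
#' written out here independently of the package solvers.
#'
#' @param n_followers Number of followers.
#' @param seed RNG seed.
#' @return A list: `game` (a [game_spec()]) and `reference` (`x_star`,
#'   `y_star`, `leader_utility`, `foc_residual`).
#' @export
generate_game_instance <- function(n_followers = 3L, seed = 1L) {
  stopifnot(n_followers >= 1L)
  set.seed(seed)
  N <- as.integer(n_followers)
  p <- stats::runif(N, 0.8, 1.5)
  q <- stats::runif(N, 0.8, 1.5)
  r <- stats::runif(N, 0, 0.2)
  a <- stats::runif(N, 1, 2)
  k <- stats::runif(N, 0.5, 1.5)
  e <- stats::runif(N, 0.05, 0.15)
  g <- stats::runif(N, 0.02, 0.08)
  lb <- c(0.3, 2)   # p*x - r > 0 on the whole interval
  y_of <- function(x) (p * x - r) / q
  marg <- function(x) sum(a * k * (p / q) * exp(-k * y_of(x)))
  cost_c <- sum(e * p / q + g)
  u <- stats::runif(1, 0.2, 0.8)
  lambda2 <- (u * marg(lb[1]) + (1 - u) * marg(lb[2])) / cost_c
  game <- game_spec(leader_bounds = lb, n_followers = N,
                    follower_bounds = c(0, 10),
                    lambda1 = 1, lambda2 = lambda2,
                    p = p, q = q, r = r, a = a, k = k, e = e, g = g)
  foc <- function(x) marg(x) - lambda2 * cost_c
  x_star <- stats::uniroot(foc, lb, tol = 1e-12)$root
  y_star <- y_of(x_star)
  list(game = game,
       reference = list(
         x_star = x_star, y_star = y_star,
         leader_utility = sum(1 * a * (1 - exp(-k * y_star)) -
                                lambda2 * (e * y_star + g * x_star)),
         foc_residual = abs(foc(x_star))))
}
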