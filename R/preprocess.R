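#' Preprocessing configuration
#'
#' Bundles every tunable of the cleaning chain: ocular artifact regression,
#' per-channel z-scoring, zero-phase band-pass (plus optional notch), spatial
#' filtering, windowing, and segment-validity thresholds.
#'
#' @param beta_mode `"least_squares"` (per-channel OLS slope of EEG on EOG,
#'   default) or `"fixed"` (use `beta_value` for every channel).
#' @param beta_value Fixed EOG regression coefficient (only in `"fixed"` mode).
#' @param band Two-element numeric, band-pass edges in Hz.
#' @param notch Optional notch center frequency in Hz (e.g. 50), or `NULL`.
#' @param spatial_method `"common_average"`, `"laplacian"` or `"none"`.
#' @param window_s,hop_s Segment window length and hop, seconds.
#' @param sigma_zero_policy For zero-variance channels in [standardize()]:
#'   `"error"` or `"zero_output"`.
#' @param validity_amp_uV Segment validity: maximum absolute amplitude.
#' @param validity_flat_eps Segment validity: minimum per-channel SD
#'   (flatline floor), same units as the segment data.
#' @param consistency_z Robust z-distance bound used by [assess_consistency()].
#' @param transition_hz Raised-cosine transition width of the FFT filter, Hz.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(beta_mode = c("least_squares", "fixed"),
                              beta_value = 0,
                              band = c(0.5, 40),
                              notch = NULL,
                              spatial_method = c("common_average", "laplacian", "none"),
                              window_s = 4, hop_s = 2,
                              sigma_zero_policy = c("error", "zero_output"),
                              validity_amp_uV = 100,
                              validity_flat_eps = 1e-6,
                              consistency_z = 3,
                              transition_hz = 0.5) {
  beta_mode <- match.arg(beta_mode)
  spatial_method <- match.arg(spatial_method)
  sigma_zero_policy <- match.arg(sigma_zero_policy)
  stopifnot(length(band) == 2L, band[1] >= 0, band[2] > band[1],
            window_s > 0, hop_s > 0, is.finite(beta_value))
  structure(list(beta_mode = beta_mode, beta_value = beta_value, band = band,
                 notch = notch, spatial_method = spatial_method,
                 window_s = window_s, hop_s = hop_s,
                 sigma_zero_policy = sigma_zero_policy,
                 validity_amp_uV = validity_amp_uV,
                 validity_flat_eps = validity_flat_eps,
                 consistency_z = consistency_z,
                 transition_hz = transition_hz),
            class = "preprocess_config")
}

#' Regress the EOG channel out of every EEG channel
#'
#' Implements ocular artifact reduction by subtraction of a scaled EOG
#' reference: `clean = raw - beta * EOG`. In `"least_squares"` mode `beta` is
#' the ordinary least-squares slope of each EEG channel on the EOG channel; in
#' `"fixed"` mode a single supplied coefficient is used for all channels. The
#' EOG channel itself is removed from the output.
#'
#' @param rec An [eeg_recording()] with `eog_index` set.
#' @param cfg A [preprocess_config()].
#' @return A list: `rec` (cleaned recording, EOG channel dropped) and `beta`
#'   (named per-channel coefficients).
#' @export
remove_eog <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$eog_index)) {
    if (cfg$beta_mode == "fixed") {
      warning("no EOG channel in recording; returning input unchanged")
      return(list(rec = rec, beta = setNames(rep(NA_real_, n_channels(rec)),
                                             rec$channel_labels)))
    }
    stop("least_squares EOG removal requires an EOG channel (eog_index)")
  }
  eog <- rec$data[rec$eog_index, ]
  keep <- setdiff(seq_len(n_channels(rec)), rec$eog_index)
  eeg <- rec$data[keep, , drop = FALSE]
  if (cfg$beta_mode == "fixed") {
    beta <- rep(cfg$beta_value, length(keep))
  } else {
    ec <- eog - mean(eog)
    denom <- sum(ec^2)
    if (denom <= 0) stop("zero-variance EOG channel: beta undefined")
    beta <- as.numeric(eeg %*% ec) / denom   # ec sums to 0: centered slope
  }
  clean <- eeg - outer(beta, eog)
  names(beta) <- rec$channel_labels[keep]
  out <- eeg_recording(clean, rec$fs, rec$channel_labels[keep],
                       session_id = rec$session_id, t0 = rec$t0)
  list(rec = out, beta = beta)
}

#' Per-channel z-scoring
#'
#' Each channel is centered and scaled by its population mean and standard
#' deviation over the full record, so downstream stages see unit-variance
#' signals regardless of per-session gain differences.
#'
#' @inheritParams remove_eog
#' @return A list: `rec` (standardized recording) and `stats` (list with
#'   per-channel `mu` and `sigma`).
#' @export
standardize <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  mu <- rowMeans(x)
  sigma <- sqrt(rowMeans((x - mu)^2))
  z <- x - mu
  if (any(sigma == 0)) {
    if (cfg$sigma_zero_policy == "error") {
      stop("zero-variance channel(s): ",
           paste(rec$channel_labels[sigma == 0], collapse = ", "))
    }
    # zero_output: flat channels become all-zero
    z[sigma == 0, ] <- 0
    sigma_safe <- ifelse(sigma == 0, 1, sigma)
  } else {
    sigma_safe <- sigma
  }
  out <- rec
  out$data <- z / sigma_safe
  rownames(out$data) <- rec$channel_labels
  list(rec = out,
       stats = list(mu = setNames(mu, rec$channel_labels),
                    sigma = setNames(sigma, rec$channel_labels)))
}

# real, even FFT gain mask evaluated at |f|; raised-cosine edges of width tw
fft_gain <- function(freqs, band, notch, tw) {
  ramp <- function(f, edge, rising) {
    # 0 below edge-tw, 1 above edge (rising); cosine-tapered between
    g <- (1 - cos(pi * pmin(pmax((f - (edge - tw)) / tw, 0), 1))) / 2
    if (rising) g else 1 - g
  }
  g <- rep(1, length(freqs))
  if (band[1] > 0) g <- g * ramp(freqs, band[1], rising = TRUE)
  g <- g * ramp(freqs, band[2] + tw, rising = FALSE)
  if (!is.null(notch)) {
    dip <- ramp(freqs, notch - tw, rising = FALSE) +
      ramp(freqs, notch + 2 * tw, rising = TRUE)
    g <- g * pmin(dip, 1)
  }
  g
}

#' Zero-phase band-pass (and optional notch) filtering
#'
#' Filtering is done in the frequency domain: each channel's spectrum is
#' multiplied by a real, symmetric gain mask (unit gain in the passband,
#' raised-cosine transitions of width `cfg$transition_hz`, zero elsewhere),
#' which is zero-phase by construction.
#'
#' @inheritParams remove_eog
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (cfg$band[2] >= nyq) {
    stop(sprintf("upper band edge %g Hz >= Nyquist %g Hz", cfg$band[2], nyq))
  }
  n <- n_samples(rec)
  k <- 0:(n - 1)
  freqs <- pmin(k, n - k) * rec$fs / n   # |f| for each FFT bin
  g <- fft_gain(freqs, cfg$band, cfg$notch, cfg$transition_hz)
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(x) {
    Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  }))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Spatial filtering
#'
#' `"common_average"` subtracts the instantaneous mean across channels;
#' `"laplacian"` subtracts the mean of each channel's `k` nearest neighbours
#' (requires 2-D positions); `"none"` is the identity.
#'
#' @inheritParams remove_eog
#' @param positions Optional `n_channels x 2` coordinate matrix (needed for
#'   the laplacian); typically `load_montage(...)$positions`.
#' @param k Number of laplacian neighbours.
#' @return The spatially filtered [eeg_recording()].
#' @export
spatial_filter <- function(rec, cfg = preprocess_config(), positions = NULL,
                           k = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- cfg$spatial_method
  if (method == "none") return(rec)
  nc <- n_channels(rec)
  out <- rec
  if (method == "common_average") {
    if (nc < 2L) stop("common_average needs >= 2 channels")
    out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  } else {
    if (is.null(positions)) stop("laplacian requires channel positions")
    positions <- as.matrix(positions)
    if (nc < 4L || nrow(positions) != nc) {
      stop("laplacian needs >= 4 channels with one position per channel")
    }
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    ref <- t(vapply(seq_len(nc), function(i) {
      nb <- order(d[i, ])[seq_len(min(k, nc - 1L))]
      colMeans(rec$data[nb, , drop = FALSE])
    }, numeric(n_samples(rec))))
    out$data <- rec$data - ref
  }
  rownames(out$data) <- rec$channel_labels
  out
}

#' Cut a recording into fixed-length segments
#'
#' Sliding windows of `round(window_s * fs)` samples at stride
#' `round(hop_s * fs)`. Returns a `segment_set`: a 3-D array
#' `[segment, channel, sample]` with per-segment validity flags (all `TRUE`
#' until [quality_score()] is applied), labels, and session ids.
#'
#' @inheritParams remove_eog
#' @param label Optional class label attached to every segment.
#' @return A `segment_set` object.
#' @export
segment <- function(rec, cfg = preprocess_config(), label = NA) {
  stopifnot(inherits(rec, "eeg_recording"))
  win <- round(cfg$window_s * rec$fs)
  hop <- round(cfg$hop_s * rec$fs)
  stopifnot(win >= 1, hop >= 1)
  n <- n_samples(rec)
  n_seg <- if (n >= win) (n - win) %/% hop + 1L else 0L
  if (n_seg == 0L) {
    warning(sprintf("record (%d samples) shorter than window (%d): 0 segments",
                    n, win))
  }
  segs <- array(0, dim = c(n_seg, n_channels(rec), win))
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1L) * hop
    segs[s, , ] <- rec$data[, (i0 + 1L):(i0 + win), drop = FALSE]
  }
  segment_set(segs, labels = rep(label, n_seg),
              session_ids = rep(rec$session_id, n_seg), fs = rec$fs,
              channel_labels = rec$channel_labels)
}

#' Construct a segment set
#'
#' @param segments 3-D array `[segment, channel, sample]`.
#' @param labels Optional per-segment class labels.
#' @param valid Logical validity flags (default all `TRUE`).
#' @param session_ids Per-segment session identifiers.
#' @param fs Sampling rate of the windows, Hz.
#' @param channel_labels Channel names.
#' @return A `segment_set` object.
#' @export
segment_set <- function(segments, labels = NULL, valid = NULL,
                        session_ids = NULL, fs = NA_real_,
                        channel_labels = NULL) {
  stopifnot(length(dim(segments)) == 3L)
  n <- dim(segments)[1L]
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(labels)) labels <- rep(NA, n)
  if (is.null(session_ids)) session_ids <- rep(NA_character_, n)
  stopifnot(length(valid) == n, length(labels) == n, length(session_ids) == n)
  structure(list(segments = segments, labels = labels, valid = valid,
                 session_ids = session_ids, fs = fs,
                 channel_labels = channel_labels),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_set> %d segments x %d ch x %d samples (%d valid)\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' Combine segment sets
#' @param ... `segment_set` objects with identical channel/window shapes.
#' @return A single `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "segment_set")) {
    sets <- sets[[1L]]
  }
  dims <- vapply(sets, function(s) dim(s$segments)[2:3], numeric(2))
  stopifnot(all(dims[1, ] == dims[1, 1]), all(dims[2, ] == dims[2, 1]))
  total <- sum(vapply(sets, function(s) dim(s$segments)[1L], integer(1)))
  segs <- array(0, dim = c(total, dims[1, 1], dims[2, 1]))
  at <- 0L
  for (s in sets) {
    k <- dim(s$segments)[1L]
    if (k > 0L) segs[at + seq_len(k), , ] <- s$segments
    at <- at + k
  }
  segment_set(segs,
              labels = unlist(lapply(sets, `[[`, "labels")),
              valid = unlist(lapply(sets, `[[`, "valid")),
              session_ids = unlist(lapply(sets, `[[`, "session_ids")),
              fs = sets[[1L]]$fs, channel_labels = sets[[1L]]$channel_labels)
}

#' Session consistency ratio
#'
#' The score is the fraction of sessions flagged consistent:
#' `n_consistent / n_sessions`. Flags typically come from
#' [assess_consistency()], but any criterion can supply them.
#'
#' @param session_flags Logical vector, one flag per session.
#' @return A list: `consistency_score`, `n_consistent_sessions`, `n_sessions`.
#' @export
consistency_score <- function(session_flags) {
  stopifnot(is.logical(session_flags), length(session_flags) >= 1L,
            !anyNA(session_flags))
  list(consistency_score = mean(session_flags),
       n_consistent_sessions = sum(session_flags),
       n_sessions = length(session_flags))
}

#' Flag sessions with consistent band-power profiles
#'
#' Each session is summarized by its per-channel log band powers (delta,
#' theta, alpha, beta). A session is consistent when its mean robust
#' z-distance (median/MAD across sessions, averaged over features) from the
#' across-session median profile is at most `z`; the mean is used rather than
#' the per-feature maximum because MAD scale estimates from a handful of
#' sessions are noisy.
#'
#' @param recordings List of [eeg_recording()]s, one per session.
#' @param z Robust z-distance bound (default 3).
#' @return Logical vector of per-session consistency flags.
#' @export
assess_consistency <- function(recordings, z = 3) {
  stopifnot(length(recordings) >= 1L)
  feats <- t(vapply(recordings, function(r) {
    bp <- band_powers(r$data, r$fs)
    log(as.numeric(bp) + 1e-12)
  }, numeric(length(band_powers(recordings[[1L]]$data,
                                recordings[[1L]]$fs)))))
  med <- apply(feats, 2L, stats::median)
  scale <- apply(feats, 2L, stats::mad)
  scale[scale == 0] <- apply(feats, 2L, stats::sd)[scale == 0]
  scale[scale == 0] <- 1e-9   # identical columns: any deviation is huge
  dev <- abs(sweep(feats, 2L, med))
  zmat <- sweep(dev, 2L, scale, "/")
  rowMeans(zmat) <= z
}

#' Band power summary
#'
#' Periodogram power of each channel integrated over the canonical EEG bands.
#'
#' @param x Channels-by-samples numeric matrix (or a vector).
#' @param fs Sampling rate, Hz.
#' @param bands Named list of `(low, high)` Hz pairs.
#' @return Matrix `channels x bands` of summed periodogram power.
#' @export
band_powers <- function(x, fs,
                        bands = list(delta = c(1, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30))) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  nf <- n %/% 2L
  freqs <- (1:nf) * fs / n
  out <- matrix(0, nrow(x), length(bands),
                dimnames = list(rownames(x), names(bands)))
  for (i in seq_len(nrow(x))) {
    p <- Mod(stats::fft(x[i, ]))^2 / n
    p <- p[2:(nf + 1L)]
    for (b in seq_along(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
      out[i, b] <- sum(p[sel])
    }
  }
  out
}

#' Segment validity and quality ratio
#'
#' A segment is valid iff its maximum absolute amplitude does not exceed
#' `cfg$validity_amp_uV` and no channel is flatlined (per-channel SD at or
#' above `cfg$validity_flat_eps`). The quality score is the valid fraction.
#'
#' @param segs A `segment_set`.
#' @inheritParams remove_eog
#' @return A list: `quality_score`, `n_valid_segments`, `n_segments`, and
#'   `valid` (per-segment flags).
#' @export
quality_score <- function(segs, cfg = preprocess_config()) {
  stopifnot(inherits(segs, "segment_set"))
  n <- dim(segs$segments)[1L]
  if (n == 0L) stop("empty segment set")
  valid <- vapply(seq_len(n), function(s) {
    w <- segs$segments[s, , , drop = TRUE]
    if (is.null(dim(w))) w <- matrix(w, nrow = dim(segs$segments)[2L])
    amp_ok <- max(abs(w)) <= cfg$validity_amp_uV
    sds <- apply(w, 1L, stats::sd)
    amp_ok && all(sds >= cfg$validity_flat_eps)
  }, logical(1))
  list(quality_score = mean(valid), n_valid_segments = sum(valid),
       n_segments = n, valid = valid)
}

#' Full preprocessing chain for one session
#'
#' Applies, in order: EOG regression, z-scoring, band-pass/notch filtering,
#' spatial filtering, montage alignment, and segmentation. Segment validity
#' (amplitude ceiling, flatline floor) is judged on the EOG-cleaned signal
#' *before* z-scoring, where the microvolt amplitude threshold is meaningful.
#'
#' @inheritParams remove_eog
#' @param montage Optional `eeg_montage` for alignment.
#' @param label Optional class label for the produced segments.
#' @return A list: `segments` (a `segment_set` with validity flags applied),
#'   `beta`, `stats`, `quality` (the [quality_score()] output).
#' @export
preprocess_session <- function(rec, cfg = preprocess_config(), montage = NULL,
                               label = NA) {
  cleaned <- if (!is.null(rec$eog_index)) {
    tryCatch(remove_eog(rec, cfg), error = function(e) {
      if (!grepl("zero-variance EOG", conditionMessage(e))) stop(e)
      # flat EOG (e.g. a blink-free stretch): nothing to regress out;
      # drop the channel and continue
      warning("flat EOG channel: regression skipped")
      keep <- setdiff(seq_len(n_channels(rec)), rec$eog_index)
      list(rec = eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                               rec$channel_labels[keep],
                               session_id = rec$session_id, t0 = rec$t0),
           beta = setNames(rep(0, length(keep)), rec$channel_labels[keep]))
    })
  } else {
    list(rec = rec, beta = NULL)
  }
  raw_segs <- segment(cleaned$rec, cfg, label = label)
  quality <- quality_score(raw_segs, cfg)
  std <- standardize(cleaned$rec, cfg)
  filt <- bandpass_filter(std$rec, cfg)
  pos <- if (!is.null(montage)) montage$positions else NULL
  spat <- spatial_filter(filt, cfg, positions = pos)
  if (!is.null(montage)) spat <- align_montage(spat, montage)
  segs <- segment(spat, cfg, label = label)
  segs$valid <- quality$valid
  list(segments = segs, beta = cleaned$beta, stats = std$stats,
       quality = quality)
}
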