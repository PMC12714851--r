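# small deterministic fixtures shared across test files

make_rec <- function(data, fs = 250, labels = NULL, ...) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(data)))
  eeg_recording(data, fs, labels, ...)
}

sine_rec <- function(freq, fs = 256, dur = 4, n_ch = 1L, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  make_rec(matrix(rep(amp * sin(2 * pi * freq * t), n_ch),
                  nrow = n_ch, byrow = TRUE), fs = fs)
}

# dominant periodogram frequency of a numeric vector
peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:(n %/% 2)
  (which.max(p[half]) + half[1L] - 2L) * fs / n
}

rms <- function(x) sqrt(mean(x^2))
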