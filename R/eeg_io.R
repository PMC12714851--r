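#' EEG recordings
#'
#' An `eeg_recording` holds a channels-by-samples numeric matrix in microvolts
#' together with its sampling rate and channel labels. Sample index is 0-based
#' in time: sample `t` (column `t + 1`) occurred at `t / fs` seconds.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param eog_index Optional 1-based row index of an EOG channel.
#' @param session_id Identifier string.
#' @param t0 Optional acquisition start time (POSIXct or string), metadata only.
#' @param nan_policy What to do with non-finite samples: `"error"` (default)
#'   or `"zero"` (replace with 0 and warn).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          eog_index = NULL, session_id = "s1", t0 = NULL,
                          nan_policy = c("error", "zero")) {
  nan_policy <- match.arg(nan_policy)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels)) {
    stop(sprintf("channel count mismatch: %d data rows vs %d labels",
                 nrow(data), length(channel_labels)))
  }
  if (!all(is.finite(data))) {
    if (nan_policy == "error") {
      stop("recording contains non-finite samples (nan_policy = 'error')")
    }
    warning("non-finite samples replaced with 0 (nan_policy = 'zero')")
    data[!is.finite(data)] <- 0
  }
  if (!is.null(eog_index)) {
    eog_index <- as.integer(eog_index)
    stopifnot(length(eog_index) == 1L, eog_index >= 1L, eog_index <= nrow(data))
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         eog_index = eog_index, session_id = session_id, t0 = t0),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.2f s)%s\n",
              x$session_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (is.null(x$eog_index)) "" else
                sprintf(", EOG = %s", x$channel_labels[x$eog_index])))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Read an EEG recording
#'
#' Two dialects are supported: `"edf"` (European Data Format, 16-bit) and
#' `"matrix"`, a delimited text matrix with one header row of channel labels
#' and channels as columns. Channel order is always file order; nothing is
#' silently reordered.
#'
#' @param path Input file.
#' @param format `"edf"` or `"matrix"`.
#' @param fs Sampling rate in Hz; required for `"matrix"` (EDF stores it).
#' @param labels Optional channel labels overriding the file header
#'   (`"matrix"` only).
#' @param nan_policy Passed to [eeg_recording()].
#' @param ... Further arguments to [eeg_recording()] (`eog_index`,
#'   `session_id`, ...).
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("edf", "matrix"), fs = NULL,
                           labels = NULL, nan_policy = "error", ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "edf") {
    edf <- read_edf_raw(path)
    if (!is.null(fs) && abs(fs - edf$fs) > 1e-9) {
      stop(sprintf("fs argument (%g) disagrees with EDF header (%g)", fs, edf$fs))
    }
    return(eeg_recording(edf$data, edf$fs, edf$labels,
                         nan_policy = nan_policy, ...))
  }
  if (is.null(fs)) stop("matrix format requires fs")
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  file_labels <- colnames(tab)
  data <- t(as.matrix(tab))
  if (is.null(labels)) {
    labels <- file_labels
  } else if (length(labels) != nrow(data)) {
    stop(sprintf("label/column mismatch: %d labels vs %d columns",
                 length(labels), nrow(data)))
  }
  eeg_recording(data, fs, labels, nan_policy = nan_policy, ...)
}

#' Write an EEG recording
#'
#' The `"matrix"` dialect is lossless up to decimal printing (15 significant
#' digits); `"edf"` quantizes each channel to 16 bits over its own physical
#' range, so round trips agree within one quantization step.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @param format `"edf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) == 0L) stop("refusing to write an empty recording")
  if (format == "edf") {
    write_edf_raw(rec$data, rec$fs, rec$channel_labels, path)
  } else {
    tab <- as.data.frame(t(rec$data))
    colnames(tab) <- rec$channel_labels
    utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---- minimal EDF codec ------------------------------------------------------
# EDF: 256-byte fixed header + 256 bytes per signal, then int16 little-endian
# data records. We write the whole recording as a single data record whose
# duration is n_samples / fs; the paired reader recovers fs from samples-per-
# record / record-duration. Multi-record files written elsewhere are read too.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2L, width = 1L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

# physical-range string: <= 7 chars so "-" + s also fits an 8-char field,
# guaranteed >= p so no sample clips
edf_phys_str <- function(p) {
  for (dg in 6:1) {
    v <- signif(p, dg)
    if (v < p) v <- v + 10^(floor(log10(p)) - dg + 1)  # round up, not down
    s <- formatC(v, format = "g", digits = dg, width = 1L)
    if (nchar(s) <= 7L && as.numeric(s) >= p) return(s)
  }
  stop("cannot represent physical range ", p)
}

write_edf_raw <- function(data, fs, labels, path) {
  ns <- nrow(data)
  nsamp <- ncol(data)
  if (nsamp > 30000000L) stop("recording too long for single-record EDF writer")
  phys_max <- apply(abs(data), 1L, max)
  phys_max[phys_max == 0] <- 1
  phys_max <- phys_max * 1.0001   # keep extreme sample strictly inside range
  pm_str <- vapply(phys_max, edf_phys_str, "")
  phys_max <- as.numeric(pm_str)  # exactly what the reader will parse
  dig_max <- 32767L; dig_min <- -32768L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("neuroedge synthetic subject", 80L),
    edf_pad("neuroedge recording", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + ns), 8L),
    edf_pad("", 44L),
    edf_pad(1L, 8L),
    edf_num(nsamp / fs, 8L),
    edf_pad(ns, 4L)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(
    hdr,
    field(labels, 16L),
    field(rep("", ns), 80L),
    field(rep("uV", ns), 8L),
    field(paste0("-", pm_str), 8L),
    field(pm_str, 8L),
    field(rep(dig_min, ns), 8L),
    field(rep(dig_max, ns), 8L),
    field(rep("", ns), 80L),
    field(rep(nsamp, ns), 8L),
    field(rep("", ns), 32L)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (i in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (2 * phys_max[i])
    dig <- as.integer(round((data[i, ] + phys_max[i]) * scale) + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  num <- function(w) as.numeric(rd(w))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  num(8L); rd(44L)
  n_rec <- num(8L)
  rec_dur <- num(8L)
  ns <- as.integer(num(4L))
  if (is.na(ns) || ns < 1L) stop("unparseable EDF header")
  per <- function(w, as_num = FALSE) {
    v <- vapply(seq_len(ns), function(i) rd(w), "")
    if (as_num) as.numeric(v) else trimws(v)
  }
  labels <- per(16L)
  per(80L); per(8L)
  phys_min <- per(8L, TRUE); phys_max <- per(8L, TRUE)
  dig_min <- per(8L, TRUE); dig_max <- per(8L, TRUE)
  per(80L)
  spr <- as.integer(per(8L, TRUE))
  per(32L)
  if (length(unique(spr)) != 1L) {
    stop("EDF with per-signal sampling rates is not supported")
  }
  fs <- spr[1L] / rec_dur
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    m <- matrix(0, ns, spr[1L])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(dig) != spr[i]) stop("EDF data truncated")
      g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      m[i, ] <- phys_min[i] + (dig - dig_min[i]) * g
    }
    chunks[[r]] <- m
  }
  list(data = do.call(cbind, chunks), fs = fs, labels = labels)
}

#' Reorder a recording's channels to a montage
#'
#' Channels are matched to montage labels case-insensitively and reordered to
#' montage order; channels not in the montage are dropped with a warning. A
#' montage label missing from the recording is an error.
#'
#' @param rec An [eeg_recording()].
#' @param montage An `eeg_montage` (see [load_montage()]).
#' @return The reordered [eeg_recording()].
#' @export
align_montage <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  idx <- match(tolower(montage$channel_labels), tolower(rec$channel_labels))
  if (anyNA(idx)) {
    stop("montage labels missing from recording: ",
         paste(montage$channel_labels[is.na(idx)], collapse = ", "))
  }
  dropped <- setdiff(seq_len(n_channels(rec)), idx)
  if (length(dropped)) {
    warning("dropping channels not in montage: ",
            paste(rec$channel_labels[dropped], collapse = ", "))
  }
  eog <- NULL
  if (!is.null(rec$eog_index) && rec$eog_index %in% idx) {
    eog <- match(rec$eog_index, idx)
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                montage$channel_labels, eog_index = eog,
                session_id = rec$session_id, t0 = rec$t0)
}
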