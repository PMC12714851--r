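#' Montage objects
#'
#' A montage is an ordered set of electrode labels, optionally with schematic
#' 2-D scalp coordinates. Two built-ins are provided: `"cap128"`, a 128-channel
#' high-density layout using extended 10-10/10-5 naming (anterior rows first,
#' left-to-right within a row), and `"wearable3"`, the three frontal contacts
#' (`Fp1`, `Fp2`, `Fpz`) of a forehead wearable collector.
#'
#' @param name Built-in montage name (`"cap128"` or `"wearable3"`) or the path
#'   to a montage file: whitespace/tab-delimited text with one electrode per
#'   row, columns `label [x y]`.
#' @return An object of class `eeg_montage` with fields `name`,
#'   `channel_labels`, `n_channels` and `positions` (an `n x 2` matrix or
#'   `NULL`).
#' @examples
#' m <- load_montage("wearable3")
#' m$channel_labels
#' @export
load_montage <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "cap128") {
    return(montage_cap128())
  }
  if (name == "wearable3") {
    return(new_montage("wearable3", c("Fp1", "Fp2", "Fpz"),
                       positions = rbind(c(-0.3, 0.95), c(0.3, 0.95), c(0, 1))))
  }
  if (!file.exists(name)) {
    stop("unknown montage name and no such file: ", name)
  }
  read_montage_file(name)
}

new_montage <- function(name, labels, positions = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("montage labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == length(labels), ncol(positions) == 2L)
    rownames(positions) <- labels
  }
  structure(
    list(name = name, channel_labels = labels,
         n_channels = length(labels), positions = positions),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %s: %d channels%s\n", x$name, x$n_channels,
              if (is.null(x$positions)) "" else " (with positions)"))
  invisible(x)
}

read_montage_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  labels <- as.character(tab[[1L]])
  positions <- NULL
  if (ncol(tab) >= 3L) {
    positions <- as.matrix(tab[, 2:3])
    storage.mode(positions) <- "double"
  }
  new_montage(basename(path), labels, positions)
}

# 128-label extended 10-10/10-5 layout, front (y = 1) to back (y = -1),
# left (x < 0) to right within each row.
montage_cap128 <- function() {
  rows <- list(
    c("Fp1", "Fpz", "Fp2"),
    c("AFp1", "AFpz", "AFp2"),
    c("AF7", "AF5", "AF3", "AF1", "AFz", "AF2", "AF4", "AF6", "AF8"),
    c("F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10"),
    c("FFC7", "FFC5", "FFC3", "FFC1", "FFCz", "FFC2", "FFC4", "FFC6", "FFC8"),
    c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10"),
    c("FCC7", "FCC5", "FCC3", "FCC1", "FCCz", "FCC2", "FCC4", "FCC6", "FCC8"),
    c("T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "T10"),
    c("CCP7", "CCP5", "CCP3", "CCP1", "CCPz", "CCP2", "CCP4", "CCP6", "CCP8"),
    c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10"),
    c("CPP7", "CPP5", "CPP3", "CPP1", "CPPz", "CPP2", "CPP4", "CPP6", "CPP8"),
    c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
    c("PPO7", "PPO5", "PPO3", "PPOz", "PPO4", "PPO6", "PPO8"),
    c("PO7", "PO5", "PO3", "PO1", "POz", "PO2", "PO4", "PO6", "PO8"),
    c("O1", "Oz", "O2"),
    c("I1", "Iz", "I2")
  )
  labels <- unlist(rows, use.names = FALSE)
  stopifnot(length(labels) == 128L)
  ys <- seq(1, -1, length.out = length(rows))
  pos <- do.call(rbind, lapply(seq_along(rows), function(r) {
    n <- length(rows[[r]])
    xs <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
    cbind(xs, rep(ys[r], n))
  }))
  new_montage("cap128", labels, pos)
}
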