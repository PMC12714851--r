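test_that("matrix format round-trips losslessly and keeps file order", {
  set.seed(101)
  rec <- make_rec(matrix(rnorm(3 * 400, sd = 30), 3), fs = 250,
                  labels = c("Fp1", "Fp2", "Fpz"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, f, "matrix")
  r2 <- read_recording(f, "matrix", fs = 250)
  expect_identical(r2$channel_labels, rec$channel_labels)
  expect_equal(r2$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(r2$fs, 250)
})

test_that("EDF round-trip stays within 16-bit quantization on random data", {
  set.seed(202)
  for (trial in 1:5) {
    nc <- sample(1:6, 1)
    ns <- sample(100:1500, 1)
    scale <- 10^runif(1, -1, 2)
    rec <- make_rec(matrix(rnorm(nc * ns, sd = scale), nc), fs = 200)
    f <- withr::local_tempfile(fileext = ".edf")
    write_recording(rec, f, "edf")
    r2 <- read_recording(f, "edf")
    qstep <- apply(abs(rec$data), 1, max) * 1.0002 * 2 / 65535
    expect_identical(r2$channel_labels, rec$channel_labels)
    expect_equal(r2$fs, rec$fs)
    for (ch in seq_len(nc)) {
      expect_lte(max(abs(r2$data[ch, ] - rec$data[ch, ])), qstep[ch] * 1.01)
    }
  }
})

test_that("a 10 Hz unit sine survives an EDF round trip spectrally", {
  rec <- sine_rec(10, fs = 256, dur = 4)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f, "edf")
  r2 <- read_recording(f, "edf")
  expect_equal(peak_freq(r2$data[1, ], 256), 10)
  expect_equal(rms(r2$data[1, ]), rms(rec$data[1, ]), tolerance = 1e-3)
})

test_that("128-channel EDF writes one signal header per channel in order", {
  m <- load_montage("cap128")
  set.seed(9)
  rec <- make_rec(matrix(rnorm(128 * 64), 128), fs = 128,
                  labels = m$channel_labels)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f, "edf")
  hdr_bytes <- as.integer(trimws(substr(readChar(f, 256, useBytes = TRUE),
                                        185, 192)))
  expect_equal(hdr_bytes, 256L * 129L)
  expect_identical(read_recording(f, "edf")$channel_labels, m$channel_labels)
})

test_that("degenerate and malformed inputs error cleanly", {
  expect_error(read_recording("no/such/file.edf", "edf"), "no such file")
  rec0 <- make_rec(matrix(numeric(0), 2, 0), fs = 100)
  f <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_recording(rec0, f, "edf"), "empty")
  expect_error(eeg_recording(matrix(1:4, 2), 0, c("a", "b")), "fs")
  expect_error(eeg_recording(matrix(1:4, 2), 100, "a"), "mismatch")
  expect_error(eeg_recording(matrix(c(1, NA, 3, 4), 2), 100, c("a", "b")),
               "non-finite")
  expect_warning(
    r <- eeg_recording(matrix(c(1, NA, 3, 4), 2), 100, c("a", "b"),
                       nan_policy = "zero"),
    "non-finite")
  expect_equal(unname(r$data[2, 1]), 0)
})

test_that("built-in montages satisfy their invariants", {
  cap <- load_montage("cap128")
  expect_equal(cap$n_channels, 128L)
  expect_equal(anyDuplicated(cap$channel_labels), 0L)
  expect_equal(dim(cap$positions), c(128L, 2L))
  w <- load_montage("wearable3")
  expect_identical(w$channel_labels, c("Fp1", "Fp2", "Fpz"))
  expect_error(load_montage("cap999"), "unknown montage")
})

test_that("montage files parse and duplicates are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Fp1 -0.3 0.95", "Fp2 0.3 0.95", "Oz 0 -1"), f)
  m <- load_montage(f)
  expect_equal(m$n_channels, 3L)
  expect_equal(unname(m$positions["Oz", ]), c(0, -1))
  writeLines(c("Fp1 0 0", "Fp1 1 1"), f)
  expect_error(load_montage(f), "unique")
})

test_that("align_montage reorders case-insensitively and drops extras", {
  rec <- make_rec(rbind(1:4, 5:8, 9:12), fs = 100,
                  labels = c("FPZ", "fp1", "Fp2"))
  out <- align_montage(rec, load_montage("wearable3"))
  expect_identical(out$channel_labels, c("Fp1", "Fp2", "Fpz"))
  expect_equal(out$data[1, ], 5:8, ignore_attr = TRUE)
  expect_equal(out$data[3, ], 1:4, ignore_attr = TRUE)

  # already in order -> identity
  rec2 <- make_rec(rbind(1:4, 5:8, 9:12), fs = 100,
                   labels = c("Fp1", "Fp2", "Fpz"))
  expect_equal(align_montage(rec2, load_montage("wearable3"))$data, rec2$data)

  # extra channel dropped with warning, missing label errors
  rec3 <- make_rec(rbind(1:4, 5:8, 9:12, 13:16), fs = 100,
                   labels = c("Fp1", "Fp2", "Fpz", "EOG"))
  expect_warning(out3 <- align_montage(rec3, load_montage("wearable3")),
                 "dropping")
  expect_equal(out3$channel_labels, c("Fp1", "Fp2", "Fpz"))
  rec4 <- make_rec(rbind(1:4), fs = 100, labels = "Cz")
  expect_error(align_montage(rec4, load_montage("wearable3")), "missing")
})
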