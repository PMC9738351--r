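test_that("EDF round trip preserves signals to quantization accuracy", {
  set.seed(5)
  fs <- 256
  data <- matrix(stats::rnorm(19 * fs * 4, sd = 20), 19)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(data, canonical_channels(), fs, path)
  raw <- read_edf(path)
  expect_equal(raw$fs, fs)
  expect_equal(raw$channel_names, canonical_channels())
  # 16-bit quantization over the physical range bounds the error
  q <- 2 * max(1, ceiling(max(abs(data)))) / 65535
  expect_lt(max(abs(raw$data - data)), q)
})

test_that("read_recording restricts to the canonical montage in order", {
  set.seed(6)
  fs <- 128
  extra <- c("ECG", canonical_channels(), "Photic")  # 21 channels
  data <- matrix(stats::rnorm(21 * fs * 2, sd = 10), 21)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(data, extra, fs, path)
  rec <- read_recording(path, "ES", "s01")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 19L)
  expect_equal(rec$channel_names, canonical_channels())
  expect_equal(rec$fs, fs)
  # row content matches the source channel of the same name (up to EDF
  # quantization)
  expect_lt(max(abs(rec$data["Cz", ] - data[match("Cz", extra), ])), 0.01)

  # rds array container with decorated channel labels
  p2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = data, fs = fs,
               channels = c("ECG", paste0("EEG ", canonical_channels(), "-REF"),
                            "Photic")), p2)
  rec2 <- read_recording(p2, "CS", "s02")
  expect_equal(rec2$channel_names, canonical_channels())
  expect_equal(rec2$data["Fp1", ], data[2, ])
})

test_that("a missing montage channel is reported by name", {
  set.seed(7)
  chans <- setdiff(canonical_channels(), "Cz")
  data <- matrix(stats::rnorm(18 * 256), 18)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(data, chans, 256, path)
  expect_error(read_recording(path, "ES", "s01"), "Cz")
})

test_that("resampling halves the rate, preserves duration and tone amplitude", {
  t <- (0:5119) / 512
  x <- matrix(rep(3 * sin(2 * pi * 10 * t), each = 19), 19, byrow = FALSE)
  rec <- eeg_recording(x, 512, canonical_channels(), "ES", "s01")
  out <- resample_recording(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 2560L)  # 10 s preserved
  # spectral peak still at 10 Hz, amplitude within 1%
  mid <- out$data[1, 513:2048]  # avoid filter edges
  expect_equal(fft_peak_hz(out$data[1, ], 256), 10, tolerance = 0.05)
  amp <- sqrt(2 * mean(mid^2))
  expect_equal(amp, 3, tolerance = 0.01)
  # identity when already at the target rate
  expect_identical(resample_recording(rec, 512), rec)
  expect_error(resample_recording(rec, -1), "positive")
})

test_that("band-pass keeps the pass band and rejects DC and high frequencies", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  mk <- function(v) eeg_recording(matrix(rep(v, each = 19), 19, byrow = FALSE),
                                  fs, canonical_channels(), "CS", "s")
  inside <- mk(2 * sin(2 * pi * 10 * t))
  out <- bandpass_recording(inside)
  core <- out$data[1, (fs + 1):(7 * fs)]
  expect_equal(sqrt(2 * mean(core^2)), 2, tolerance = 0.05)

  high <- mk(sin(2 * pi * 64 * t))
  hout <- bandpass_recording(high)
  expect_lt(sqrt(mean(hout$data[1, ]^2)) / sqrt(0.5), 0.10)

  dc <- mk(rep(5, length(t)))
  dout <- bandpass_recording(dc)
  expect_lt(sqrt(mean(dout$data[1, ]^2)) / 5, 0.05)

  expect_error(bandpass_recording(mk(t), low = 0.5, high = 128), "Nyquist")
})

test_that("resample-then-filter and filter-then-resample agree on band-limited tones", {
  fs <- 512
  t <- (0:(6 * fs - 1)) / fs
  v <- sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 20 * t)
  rec <- eeg_recording(matrix(rep(v, each = 19), 19, byrow = FALSE), fs,
                       canonical_channels(), "ES", "s")
  a <- bandpass_recording(resample_recording(rec, 256))
  b <- resample_recording(bandpass_recording(rec), 256)
  core <- 257:(5 * 256)  # interior, away from edge transients
  rms_diff <- sqrt(mean((a$data[1, core] - b$data[1, core])^2))
  expect_lt(rms_diff / sqrt(mean(a$data[1, core]^2)), 0.02)
})

test_that("segmentation produces 50%-overlap windows with the exact count", {
  fs <- 256
  rec <- eeg_recording(matrix(stats::rnorm(19 * 2560), 19), fs,
                       canonical_channels(), "PNES", "s01")
  es <- segment_epochs(rec)
  expect_equal(dim(es$data), c(3L, 19L, 1280L))
  expect_equal(es$manifest$start_sample, c(0L, 640L, 1280L))
  expect_equal(unique(es$manifest$label), "PNES")

  one <- eeg_recording(matrix(stats::rnorm(19 * 1280), 19), fs,
                       canonical_channels(), "ES", "s02")
  expect_equal(dim(segment_epochs(one)$data)[1], 1L)

  short <- eeg_recording(matrix(stats::rnorm(19 * 1000), 19), fs,
                         canonical_channels(), "ES", "s03")
  expect_warning(out <- segment_epochs(short), "shorter")
  expect_equal(dim(out$data)[1], 0L)
  expect_error(segment_epochs(short, on_short = "error"), "shorter")
})

test_that("epoch count formula matches brute-force offset enumeration", {
  set.seed(11)
  for (n in c(1280, 1281, 1919, 1920, 2559, 2560,
              sample(1280:100000, 40))) {
    brute <- length(seq(0, n - 1280, by = 640))
    expect_identical(epoch_count(n), as.integer(brute))
  }
  expect_identical(epoch_count(1279), 0L)
})

test_that("segmentation is lossless over the covered range", {
  fs <- 256
  n <- 1280 + 640 * 4 + 100  # trailing remainder discarded
  rec <- eeg_recording(matrix(stats::rnorm(19 * n), 19), fs,
                       canonical_channels(), "CS", "s01")
  es <- segment_epochs(rec)
  k <- dim(es$data)[1]
  rebuilt <- do.call(cbind, c(lapply(seq_len(k), function(i) es$data[i, , 1:640]),
                              list(es$data[k, , 641:1280])))
  expect_identical(rebuilt, unname(rec$data[, 1:(640 * k + 640)]))
})

test_that("epoch sets bind, round-trip and keep provenance", {
  fs <- 256
  mk <- function(id, lab, n) segment_epochs(
    eeg_recording(matrix(stats::rnorm(19 * n), 19), fs, canonical_channels(),
                  lab, id))
  a <- mk("s01", "ES", 2560)
  b <- mk("s02", "CS", 1920)
  both <- bind_epoch_sets(a, b)
  expect_equal(dim(both$data)[1], 5L)
  expect_equal(both$manifest$subject_id, c("s01", "s01", "s01", "s02", "s02"))
  path <- withr::local_tempfile(fileext = ".rds")
  write_epoch_set(both, path)
  expect_identical(read_epoch_set(path), both)
  expect_true(file.exists(sub("\\.rds$", ".csv", path)))
})
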