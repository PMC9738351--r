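test_that("find_extrema locates strict extrema, plateaus and monotone cases", {
  e <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(e$max_idx, 2L)
  expect_equal(e$min_idx, 4L)

  ramp <- find_extrema(seq(0, 1, length.out = 50))
  expect_length(ramp$max_idx, 0)
  expect_length(ramp$min_idx, 0)

  # plateau counts once, at its midpoint
  p <- find_extrema(c(0, 1, 1, 1, 0, -1, 0))
  expect_equal(p$max_idx, 3L)
  expect_equal(p$min_idx, 6L)

  t <- (0:255) / 256
  s <- sin(2 * pi * 4 * t)
  es <- find_extrema(s)
  expect_length(es$max_idx, 4)
  expect_length(es$min_idx, 4)
  ord <- sort(c(es$max_idx, es$min_idx))
  expect_equal(oracle_count_extrema(s), 8L)
  # maxima and minima alternate
  kinds <- ifelse(ord %in% es$max_idx, "M", "m")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("zero-crossing counting matches a sample-by-sample oracle", {
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rnorm(200)
    x[sample(200, 5)] <- 0  # exact zeros must stay transparent
    expect_identical(count_zero_crossings(x), oracle_count_zero_crossings(x))
  }
})

test_that("envelope mean of a pure tone is near zero, with offsets recovered", {
  t <- (0:2047) / 256
  a <- 1.7
  x <- a * sin(2 * pi * 8 * t)
  m <- envelope_mean(x)
  interior <- 257:(2048 - 256)
  expect_lt(max(abs(m[interior])), 0.05 * a)

  m2 <- envelope_mean(x + 3)
  expect_equal(mean(m2[interior]), 3, tolerance = 0.05 * 3 / 3)
  expect_lt(max(abs(m2[interior] - 3)), 0.05 * 3 + 0.05 * a)

  # minimum viable extrema count after boundary extension
  t2 <- (0:127) / 256
  x2 <- sin(2 * pi * 4 * t2)  # 2 maxima, 2 minima
  expect_length(envelope_mean(x2), 128)
  expect_error(envelope_mean(seq_len(100) / 10),
               class = "emdnet_monotone_residual")
})

test_that("sifting extracts the fast mode first and residual is exact", {
  t <- (0:1279) / 256
  x <- sin(2 * pi * 16 * t) + sin(2 * pi * 1 * t)
  s <- sift_imf(x, sift_config())
  expect_equal(fft_peak_hz(s$imf, 256), 16, tolerance = 0.01)
  expect_identical(s$residual, x - s$imf)
  expect_true(oracle_imf_condition(s$imf))
})

test_that("decomposition reconstructs, orders frequencies, and degenerates safely", {
  cfg <- sift_config(max_imfs = 3)
  t <- (0:1279) / 256
  x <- sin(2 * pi * 16 * t) + sin(2 * pi * 1 * t)
  dec <- emd_decompose(x, cfg)
  expect_gte(dec$n_imf, 2)
  recon <- rowSums(dec$imfs) + dec$residual
  expect_lt(max(abs(x - recon)), 1e-8 * max(abs(x)))
  peaks <- vapply(seq_len(dec$n_imf), function(i) fft_peak_hz(dec$imfs[, i], 256),
                  numeric(1))
  expect_equal(peaks[1], 16, tolerance = 0.01)
  expect_true(any(abs(peaks - 1) < 0.5))
  expect_true(all(diff(peaks) < 0))

  const <- emd_decompose(rep(2, 1280), cfg)
  expect_equal(const$n_imf, 0L)
  expect_identical(const$residual, rep(2, 1280))

  # deterministic: same input, same output, bit for bit
  expect_identical(emd_decompose(x, cfg), emd_decompose(x, cfg))
})

test_that("random band-limited signals reconstruct and satisfy the IMF condition", {
  set.seed(33)
  for (i in 1:15) {
    x <- random_bandlimited(1280) + 0.2 * stats::rnorm(1280)
    dec <- emd_decompose(x, sift_config())
    recon <- if (dec$n_imf > 0) rowSums(dec$imfs) + dec$residual else dec$residual
    expect_lt(max(abs(x - recon)), 1e-8 * max(abs(x)))
    for (j in seq_len(dec$n_imf)) {
      expect_true(oracle_imf_condition(dec$imfs[, j]))
    }
  }
})

test_that("orthogonality diagnostic reports near-orthogonal components", {
  t <- (0:1279) / 256
  x <- sin(2 * pi * 16 * t) + sin(2 * pi * 2 * t)
  o <- imf_orthogonality(emd_decompose(x, sift_config()))
  expect_equal(unname(diag(o)), rep(1, nrow(o)))
  # reported, not asserted as a hard invariant; off-diagonals should at
  # least be well below total correlation for well-separated tones
  expect_lt(max(abs(o[upper.tri(o)])), 0.5)
})

test_that("IMF tensors have fixed shape with zero-filled missing planes", {
  ep <- two_tone_epoch()
  tens <- build_imf_tensor(ep, sift_config(max_imfs = 3))
  expect_equal(dim(tens), c(19L, 1280L, 3L))
  # identical channels give identical planes
  expect_identical(tens[1, , 1], tens[10, , 1])

  ep2 <- ep
  ep2[4, ] <- 0  # constant channel: no extrema, no IMFs
  expect_warning(t2 <- build_imf_tensor(ep2, sift_config(max_imfs = 3)),
                 "zero-filled")
  expect_true(all(t2[4, , ] == 0))
  expect_false(all(t2[5, , ] == 0))
})

test_that("epoch sets decompose into tensor sets that round-trip", {
  fs <- 256
  rec <- eeg_recording(matrix(rep(two_tone_epoch()[1, ], 19 * 2), 19), fs,
                       canonical_channels(), "ES", "s01")
  es <- segment_epochs(rec)
  tens <- decompose_epochs(es, sift_config())
  expect_equal(dim(tens$data), c(3L, 19L, 1280L, 3L))
  expect_equal(tens$manifest, es$manifest)
  path <- withr::local_tempfile(fileext = ".rds")
  write_imf_tensors(tens, path)
  expect_identical(read_imf_tensors(path), tens)
})
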