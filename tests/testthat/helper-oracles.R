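# Independent oracles: deliberately naive loop/enumeration implementations,
# kept separate from the package's own code paths.

# Count strict interior extrema by scanning every sample; plateaus are
# compressed first so a flat top counts once.
oracle_count_extrema <- function(x) {
  keep <- c(TRUE, diff(x) != 0)
  xc <- x[keep]
  n <- length(xc)
  if (n < 3) return(0L)
  cnt <- 0L
  for (i in 2:(n - 1)) {
    if ((xc[i] > xc[i - 1] && xc[i] > xc[i + 1]) ||
        (xc[i] < xc[i - 1] && xc[i] < xc[i + 1])) cnt <- cnt + 1L
  }
  cnt
}

# Count sign changes, walking sample by sample and skipping exact zeros.
oracle_count_zero_crossings <- function(x) {
  last <- 0
  cnt <- 0L
  for (v in x) {
    s <- sign(v)
    if (s == 0) next
    if (last != 0 && s != last) cnt <- cnt + 1L
    last <- s
  }
  cnt
}

oracle_imf_condition <- function(x) {
  abs(oracle_count_extrema(x) - oracle_count_zero_crossings(x)) <= 1L
}

# Dominant FFT frequency (Hz) of a real signal.
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[2:floor(n / 2)]
  which.max(mag) * fs / n
}

# Amplitude of the FFT bin nearest f0 for a pure tone of length n.
fft_amplitude_at <- function(x, fs, f0) {
  n <- length(x)
  k <- round(f0 * n / fs)
  2 * Mod(stats::fft(x))[k + 1] / n
}

# Random band-limited signal: a handful of tones with random phases inside
# the EEG band.
random_bandlimited <- function(n = 1280, fs = 256, n_tones = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  freqs <- stats::runif(n_tones, 1, 30)
  amps <- stats::runif(n_tones, 0.5, 2)
  phases <- stats::runif(n_tones, 0, 2 * pi)
  colSums(amps * sin(outer(2 * pi * freqs, t) + phases))
}

# A 19 x 1280 epoch matrix with every channel the same two-tone signal.
two_tone_epoch <- function(f_hi = 16, f_lo = 1, fs = 256, n = 1280) {
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * f_hi * t) + sin(2 * pi * f_lo * t)
  matrix(rep(x, each = 19), nrow = 19)
}

# Tiny trivially separable tensors: class k carries a tone at a distinct
# frequency on every channel, plus light noise.
separable_tensors <- function(n_per_class, shape = c(19L, 128L, 3L),
                              fs = 256, seed = 1) {
  set.seed(seed)
  freqs <- c(4, 10, 24)
  n <- 3L * n_per_class
  x <- array(0, c(n, shape))
  y <- integer(n)
  t <- (seq_len(shape[2]) - 1) / fs
  i <- 0L
  for (cl in 0:2) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      y[i] <- cl
      base <- sin(2 * pi * freqs[cl + 1] * t + stats::runif(1, 0, 2 * pi))
      for (ch in seq_len(shape[1])) {
        for (p in seq_len(shape[3])) {
          x[i, ch, , p] <- base + 0.1 * stats::rnorm(shape[2])
        }
      }
    }
  }
  list(x = x, y = y)
}

# A small spec with the same layer vocabulary as the default architecture.
small_spec <- function(input_shape = c(2L, 32L, 2L), dropout = TRUE) {
  layers <- list(
    conv2d_layer(4L, c(1L, 6L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 2L), stride = c(1L, 2L), padding = "valid"),
    conv2d_layer(3L, c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    flatten_layer(),
    dense_layer(5L))
  if (dropout) layers <- c(layers, list(dropout_layer(0.3)))
  layers <- c(layers, list(dense_layer(3L, activation = "softmax")))
  model_spec(layers, input_shape = input_shape)
}

# Enumerate valid-padding window starts one by one.
oracle_valid_out_width <- function(w, k, s) {
  cnt <- 0L
  start <- 1L
  while (start + k - 1L <= w) {
    cnt <- cnt + 1L
    start <- start + s
  }
  cnt
}

# A quick random confusion matrix (possibly with empty rows compensated).
random_confusion <- function() {
  m <- matrix(stats::rpois(9, lambda = stats::runif(1, 0.5, 20)), 3, 3)
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}

# Synthetic recording shrunk for fast tests.
tiny_synth_config <- function(seed = 1, preset = "easy", duration_s = 20,
                              n_subjects_per_class = 2L) {
  synthetic_config(n_subjects_per_class = n_subjects_per_class,
                   duration_s = duration_s, preset = preset, seed = seed)
}
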