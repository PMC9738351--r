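# Seeded surrogate EEG. Each channel is a sum of class-specific narrow-band
# oscillations (Gaussian-shaped bands in the 0.5-32 Hz range) over a 1/f^beta
# colored-noise background, scaled to a configured oscillation-to-background
# power ratio and to a physiological amplitude. The class profiles are
# distinct fixtures chosen for controllable separability; they are not a
# model of ES/PNES pathophysiology.

#' Default class spectral profiles
#'
#' ES: excess slow (3-5 Hz) and fast (14-18 Hz) band power. PNES: excess
#' alpha (8-12 Hz) power with partial inter-channel phase coupling. CS:
#' background-dominated with only a weak broad alpha component. The `"hard"`
#' preset gives every class the CS profile, which removes all class
#' information and should drive any classifier to chance.
#'
#' @param preset `"easy"`, `"moderate"` or `"hard"`.
#' @return Named list of per-class component tables
#'   (`center_hz`, `bandwidth_hz`, `rel_power`, `coupling`).
#' @export
default_class_profiles <- function(preset = c("easy", "moderate", "hard")) {
  preset <- match.arg(preset)
  comp <- function(f, bw, p, couple = 0) {
    data.frame(center_hz = f, bandwidth_hz = bw, rel_power = p,
               coupling = couple)
  }
  cs <- comp(10, 4, 0.15)
  if (preset == "hard") return(list(ES = cs, PNES = cs, CS = cs))
  list(ES = rbind(comp(4, 2, 1.0), comp(16, 4, 0.8)),
       PNES = comp(10, 2, 1.0, couple = 0.7),
       CS = cs)
}

#' Synthetic cohort configuration
#'
#' Defaults define the desk-scale study condition: 4 subjects per class, 60 s
#' per subject at 256 Hz, which yields 23 five-second 50%-overlap epochs per
#' subject (276 in total) — enough to train the classifier on one CPU in
#' minutes. Difficulty presets set the oscillation-to-background power ratio
#' (`snr`): easy 2.0, moderate 0.6, hard 2.0 but with identical class
#' profiles (no class signal at all).
#'
#' @param n_subjects_per_class Subjects per class (default 4).
#' @param duration_s Recording length per subject in seconds (default 60).
#' @param fs Sampling rate; the pipeline assumes 256 Hz.
#' @param preset Difficulty preset; fixes `snr` and `class_profiles` unless
#'   they are given explicitly.
#' @param class_profiles Per-class component tables
#'   (see [default_class_profiles()]).
#' @param snr Oscillation strength scale (> 0): a component with relative
#'   power `r` carries `r * snr` times the (unit) background power.
#' @param background_beta Spectral slope of the 1/f^beta background
#'   (default 1).
#' @param target_rms_uv Overall per-channel RMS amplitude in microvolts.
#' @param seed Master seed; per-subject streams are derived from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_class = 4L, duration_s = 60,
                             fs = 256, preset = c("easy", "moderate", "hard"),
                             class_profiles = NULL, snr = NULL,
                             background_beta = 1, target_rms_uv = 10,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(snr)) snr <- c(easy = 2.0, moderate = 0.6, hard = 2.0)[[preset]]
  if (is.null(class_profiles)) class_profiles <- default_class_profiles(preset)
  stopifnot(n_subjects_per_class >= 1, duration_s > 0, fs > 0, snr > 0)
  for (cl in names(class_profiles)) {
    p <- class_profiles[[cl]]
    if (any(p$center_hz <= 0.5 | p$center_hz >= 32)) {
      stop("parameter error: component frequencies must lie in (0.5, 32) Hz",
           call. = FALSE)
    }
  }
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 duration_s = duration_s, fs = fs, preset = preset,
                 class_profiles = class_profiles, snr = snr,
                 background_beta = background_beta,
                 target_rms_uv = target_rms_uv, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic 31-bit stream seed from the master seed and a stream index.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 65536) * 32749 + stream * 7919 + 12345) %% 2147483647
}

# Colored noise with power spectral density proportional to f^(-beta).
colored_noise <- function(n, fs, beta) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequency
  shape <- c(0, f[-1]^(-beta / 2))
  Re(stats::fft(spec * shape, inverse = TRUE)) / n
}

# Narrow-band Gaussian process centered at f0 with given bandwidth (full
# width at half of the Gaussian spectral weight's sigma interpretation).
narrowband_noise <- function(n, fs, f0, bw) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- exp(-0.5 * ((f - f0) / (bw / 2))^2)
  Re(stats::fft(spec * shape, inverse = TRUE)) / n
}

scale_to_power <- function(x, p) {
  pw <- mean(x^2)
  if (pw == 0) return(x)
  x * sqrt(p / pw)
}

#' Generate one synthetic recording
#'
#' 19 channels at `cfg$fs`. Oscillatory components use randomized phases per
#' channel; a component with `coupling` c in (0, 1] mixes a channel-shared
#' realization (weight `sqrt(c)`) with an independent one, emulating
#' inter-channel phase coupling. Amplitudes get mild per-channel log-normal
#' variation and the channel is scaled to `cfg$target_rms_uv` RMS, keeping
#' samples well inside +/-100 microvolts.
#'
#' @param label Class label (`"ES"`, `"PNES"`, `"CS"`).
#' @param cfg A [synthetic_config()].
#' @param subject_seed Stream seed for this subject (see [derive_seed()]);
#'   the same seed reproduces the identical recording bit-for-bit.
#' @param subject_id Identifier stored in the recording.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(label, cfg, subject_seed,
                               subject_id = paste0(label, "-", subject_seed)) {
  label <- class_levels()[class_code(label) + 1L]
  profile <- cfg$class_profiles[[label]]
  if (is.null(profile)) stop("parameter error: no profile for class ", label,
                             call. = FALSE)
  n <- round(cfg$duration_s * cfg$fs)
  set.seed(subject_seed)
  nch <- 19L
  # component power relative to the unit-power background is rel_power * snr
  rel <- profile$rel_power

  shared <- lapply(seq_len(nrow(profile)), function(k)
    narrowband_noise(n, cfg$fs, profile$center_hz[k], profile$bandwidth_hz[k]))
  data <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    bg <- scale_to_power(colored_noise(n, cfg$fs, cfg$background_beta), 1)
    osc <- numeric(n)
    for (k in seq_len(nrow(profile))) {
      cpl <- profile$coupling[k]
      comp <- narrowband_noise(n, cfg$fs, profile$center_hz[k],
                               profile$bandwidth_hz[k])
      if (cpl > 0) {
        comp <- sqrt(cpl) * shared[[k]] + sqrt(1 - cpl) * comp
      }
      gain <- exp(stats::rnorm(1, 0, 0.1))  # mild per-channel variation
      osc <- osc + scale_to_power(comp, rel[k] * cfg$snr) * gain
    }
    data[ch, ] <- scale_to_power(bg + osc, cfg$target_rms_uv^2)
  }
  rownames(data) <- canonical_channels()
  eeg_recording(data, cfg$fs, canonical_channels(), label, subject_id)
}

#' Generate a labeled synthetic cohort
#'
#' @param cfg A [synthetic_config()].
#' @param cohort `"balanced"` (default: `n_subjects_per_class` per class) or
#'   `"clinical"` (the 42/42/19 ES/PNES/CS imbalance of the motivating
#'   cohort, scaled by `n_subjects_per_class / 4`).
#' @return A `synthetic_dataset`: list of `recordings`, a `manifest` data
#'   frame, and the generating config (regenerating from the manifest is
#'   bit-exact).
#' @export
generate_dataset <- function(cfg = synthetic_config(),
                             cohort = c("balanced", "clinical")) {
  cohort <- match.arg(cohort)
  counts <- if (cohort == "balanced") {
    stats::setNames(rep(cfg$n_subjects_per_class, 3), class_levels())
  } else {
    round(c(ES = 42, PNES = 42, CS = 19) * cfg$n_subjects_per_class / 4)
  }
  recordings <- list()
  rows <- list()
  stream <- 0L
  for (cl in class_levels()) {
    for (s in seq_len(counts[[cl]])) {
      stream <- stream + 1L
      sseed <- derive_seed(cfg$seed, stream)
      sid <- sprintf("%s%02d", cl, s)
      rec <- generate_recording(cl, cfg, sseed, subject_id = sid)
      recordings[[length(recordings) + 1L]] <- rec
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sid, label = cl, stream_seed = sseed,
                   duration_s = cfg$duration_s, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(recordings = recordings, manifest = manifest, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d recordings (%s preset, seed %d)\n",
              length(x$recordings), x$config$preset, x$config$seed))
  print(table(x$manifest$label))
  invisible(x)
}

#' Smoothed periodogram power spectral density
#'
#' Thin wrapper over [stats::spec.pgram()] (detrended, tapered, Daniell
#' smoothed) returning frequency in Hz and power density; used by the
#' generator's spectral diagnostics and tests.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param spans Daniell smoother spans (see [stats::spec.pgram()]).
#' @return Data frame with `freq_hz` and `power`.
#' @export
psd_estimate <- function(x, fs, spans = 11) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = spans,
                          taper = 0.1, detrend = TRUE, plot = FALSE)
  data.frame(freq_hz = sp$freq, power = sp$spec)
}

#' Log-log spectral slope over a band
#'
#' Least-squares slope of log power vs log frequency; for a 1/f^beta
#' background the slope estimates -beta.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Frequency band in Hz over which to regress.
#' @return Scalar slope.
#' @export
spectral_slope <- function(x, fs, band = c(1, 30)) {
  psd <- psd_estimate(x, fs)
  sel <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2] & psd$power > 0
  stats::coef(stats::lm(log(power) ~ log(freq_hz), data = psd[sel, ]))[[2]]
}

#' Band power fraction
#'
#' Fraction of total power in `[f0 - half, f0 + half]`, from the smoothed
#' periodogram.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate.
#' @param f0 Band center in Hz.
#' @param half Half-width in Hz.
#' @return Scalar in \[0, 1\].
#' @export
band_power_fraction <- function(x, fs, f0, half) {
  psd <- psd_estimate(x, fs)
  sel <- psd$freq_hz >= f0 - half & psd$freq_hz <= f0 + half
  sum(psd$power[sel]) / sum(psd$power)
}

#' Write a synthetic dataset to disk
#'
#' One file per recording (EDF by default, or the RDS array container), plus
#' `manifest.csv` and a JSON copy of the generating configuration.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory.
#' @param format `"edf"` or `"rds"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("edf", "rds")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$recordings))
  for (i in seq_along(ds$recordings)) {
    rec <- ds$recordings[[i]]
    paths[i] <- file.path(dir, paste0(rec$subject_id, ".", format))
    if (format == "edf") {
      write_edf(rec$data, rec$channel_names, rec$fs, paths[i],
                patient = rec$subject_id)
    } else {
      saveRDS(list(data = rec$data, fs = rec$fs, channels = rec$channel_names,
                   label = rec$label, subject_id = rec$subject_id), paths[i])
    }
  }
  manifest <- cbind(ds$manifest, file = basename(paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- ds$config
  cfg$class_profiles <- lapply(cfg$class_profiles, as.list)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
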