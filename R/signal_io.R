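#' Canonical 10-20 channel order
#'
#' The fixed 19-channel montage used throughout the package. Every
#' [eeg_recording()] is stored with its rows in exactly this order, so that
#' epoch arrays and IMF tensors are reproducible across readers and machines.
#'
#' @return Character vector of 19 channel names.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Class labels for the three-way problem
#'
#' Integer codes are fixed: ES = 0, PNES = 1, CS = 2.
#'
#' @return Character vector `c("ES", "PNES", "CS")`.
#' @export
class_levels <- function() c("ES", "PNES", "CS")

#' Convert a label to its integer code
#'
#' @param label Character label among `"ES"`, `"PNES"`, `"CS"`, or an integer
#'   code already in `0:2`.
#' @return Integer code in `0:2`.
#' @export
class_code <- function(label) {
  if (is.numeric(label)) {
    code <- as.integer(label)
    if (any(!code %in% 0:2)) stop("class code must be in 0:2", call. = FALSE)
    return(code)
  }
  idx <- match(toupper(as.character(label)), class_levels())
  if (any(is.na(idx))) {
    stop("unknown class label: ", paste(label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

#' Construct a multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector naming the rows of `data`.
#' @param label Class label (`"ES"`, `"PNES"` or `"CS"`).
#' @param subject_id Opaque subject identifier string.
#' @param validate_montage If `TRUE` (default) the recording is restricted to
#'   the 19 canonical 10-20 channels, in canonical order; missing channels are
#'   an error.
#' @return An object of class `eeg_recording`: a list with fields
#'   `subject_id`, `label`, `channel_names`, `fs`, `data`.
#' @export
eeg_recording <- function(data, fs, channel_names, label, subject_id,
                          validate_montage = TRUE) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (length(channel_names) != nrow(data)) {
    stop("channel_names length must equal number of data rows", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("data contains non-finite values", call. = FALSE)
  label <- class_levels()[class_code(label) + 1L]
  rec <- structure(
    list(subject_id = as.character(subject_id), label = label,
         channel_names = as.character(channel_names), fs = as.numeric(fs),
         data = data),
    class = "eeg_recording")
  if (validate_montage) rec <- select_montage(rec) else rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s  label %s  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

# Normalize a raw channel label: strip "EEG " prefixes, reference suffixes
# ("-REF", "-LE", "-A1", "-A2"), whitespace and case.
normalize_channel_name <- function(nm) {
  nm <- toupper(trimws(nm))
  nm <- sub("^EEG[ _]*", "", nm)
  nm <- sub("[-_ ](REF|LE|RE|A1|A2|AVG)$", "", nm)
  gsub("[ .]", "", nm)
}

#' Restrict a recording to the canonical 19-channel montage
#'
#' Channel matching is case-insensitive and tolerant of common EDF label
#' decorations (`"EEG Fp1-REF"` matches `"Fp1"`).
#'
#' @param rec An `eeg_recording` (constructed with `validate_montage = FALSE`
#'   or coming from a reader).
#' @return The recording with exactly 19 rows in canonical order.
#' @export
select_montage <- function(rec) {
  want <- normalize_channel_name(canonical_channels())
  have <- normalize_channel_name(rec$channel_names)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("montage error: missing channel(s): ",
         paste(canonical_channels()[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- canonical_channels()
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Read an EEG recording from disk
#'
#' Supports EDF/EDF+ files (`.edf`) and the package's plain array container
#' (`.rds`: a list with elements `data` (channels x samples matrix), `fs`,
#' `channels`, and optionally `label`, `subject_id`). The returned recording is
#' restricted to the 19 canonical 10-20 channels in canonical order; the raw
#' sampling rate is preserved.
#'
#' @param path Path to an `.edf` or `.rds` file.
#' @param label Class label (`"ES"`, `"PNES"`, `"CS"`); overrides any label in
#'   the container.
#' @param subject_id Subject identifier; overrides any identifier in the file.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, label, subject_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    raw <- read_edf(path)
    eeg_recording(raw$data, raw$fs, raw$channel_names, label, subject_id)
  } else if (ext == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data) || is.null(obj$fs) || is.null(obj$channels)) {
      stop("format error: container must hold 'data', 'fs', 'channels'", call. = FALSE)
    }
    eeg_recording(obj$data, obj$fs, obj$channels, label, subject_id)
  } else {
    stop("format error: unsupported file type '", ext, "'", call. = FALSE)
  }
}

#' Resample a recording to a target rate
#'
#' Rational-ratio resampling: the signal is zero-stuffed by the numerator,
#' low-pass filtered at the lower of the two Nyquist rates with a zero-phase
#' windowed-sinc (Hamming) kernel, and decimated by the denominator. The long
#' kernel keeps pass-band gain flat to well under 1%. Upsampling is allowed
#' but reported with a message; the usual pipeline direction is downsampling
#' to 256 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate in Hz.
#' @return The recording at `target_fs`; duration preserved within one sample
#'   period.
#' @export
resample_recording <- function(rec, target_fs = 256) {
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("parameter error: target_fs must be a positive scalar", call. = FALSE)
  }
  if (target_fs == rec$fs) return(rec)
  if (target_fs > rec$fs) {
    message("upsampling from ", rec$fs, " Hz to ", target_fs, " Hz")
  }
  frac <- rational_ratio(target_fs, rec$fs)
  p <- frac[1]; q <- frac[2]
  n <- ncol(rec$data)
  n_out <- floor(n * target_fs / rec$fs)
  fs_up <- rec$fs * p
  cutoff <- min(rec$fs, target_fs) / 2
  trans <- 0.2 * cutoff
  taps <- ceiling(3.3 * fs_up / trans)
  if (taps %% 2 == 1) taps <- taps + 1
  h <- signal::fir1(taps, (cutoff - trans / 2) / (fs_up / 2), type = "low") * p
  pick <- seq(1L, by = q, length.out = n_out)
  out <- matrix(0, nrow(rec$data), n_out)
  for (i in seq_len(nrow(rec$data))) {
    up <- numeric(n * p)
    up[seq(1L, by = p, length.out = n)] <- rec$data[i, ]
    out[i, ] <- zero_phase_filter(up, h)[pick]
  }
  rownames(out) <- rec$channel_names
  rec$data <- out
  rec$fs <- target_fs
  rec
}

# Small continued-fraction rational approximation p/q of x = a/b.
rational_ratio <- function(a, b, tol = 1e-9) {
  x <- a / b
  # exact for the integer rates used in practice
  for (q in 1:4096) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < tol) return(c(p, q))
  }
  stop("cannot express rate ratio ", a, "/", b, " as a small rational",
       call. = FALSE)
}

# Zero-phase FIR band-pass kernel: cascade of a windowed-sinc (Hamming)
# high-pass with a narrow transition at the low edge and a low-pass with a
# wide transition at the high edge. Returns an odd-length symmetric kernel.
design_bandpass_kernel <- function(fs, low, high,
                                   trans_low = 0.5, trans_high = 8) {
  order_for <- function(trans) {
    n <- ceiling(3.3 * fs / trans)  # Hamming main-lobe transition rule
    if (n %% 2 == 1) n <- n + 1     # even order -> odd tap count, symmetric
    n
  }
  h_hp <- signal::fir1(order_for(trans_low), low / (fs / 2), type = "high")
  h_lp <- signal::fir1(order_for(trans_high), high / (fs / 2), type = "low")
  convolve(h_hp, rev(h_lp), type = "open")
}

# Centered (zero-phase) convolution with reflection padding at both ends.
zero_phase_filter <- function(x, h) {
  m <- (length(h) - 1L) %/% 2L
  n <- length(x)
  # reflect interior samples about each end point
  pad_l <- if (m > 0) x[pmin(n, 1L + (m:1))] else numeric(0)
  pad_r <- if (m > 0) x[pmax(1L, n - (1:m))] else numeric(0)
  xp <- c(pad_l, x, pad_r)
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(2L * m + 1L):(2L * m + n)]
}

#' Band-pass filter a recording (zero phase)
#'
#' Zero-phase FIR filtering with a windowed-sinc (Hamming) kernel: sharp
#' transition (0.5 Hz) at the low edge to reject drift and DC, wide transition
#' (8 Hz) above the pass band. The symmetric kernel is applied centered, so
#' features are not shifted in time; edges are reflection-padded.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Pass-band edges in Hz (defaults 0.5 and 32).
#' @return The filtered recording, same shape.
#' @export
bandpass_recording <- function(rec, low = 0.5, high = 32) {
  if (high >= rec$fs / 2) {
    stop("parameter error: high edge (", high, " Hz) must be below Nyquist (",
         rec$fs / 2, " Hz)", call. = FALSE)
  }
  if (low <= 0 || low >= high) {
    stop("parameter error: need 0 < low < high", call. = FALSE)
  }
  h <- design_bandpass_kernel(rec$fs, low, high)
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- zero_phase_filter(rec$data[i, ], h)
  }
  rec
}

#' Number of epochs obtainable from a recording
#'
#' Closed form for fixed-length windows with a fixed hop: for `n` samples,
#' window `len` and hop `hop`, the count is `floor((n - len) / hop) + 1`
#' (0 when `n < len`).
#'
#' @param n_samples Recording length in samples.
#' @param epoch_len Window length in samples (default 1280 = 5 s at 256 Hz).
#' @param hop Hop in samples (default 640 = 50% overlap).
#' @return Integer epoch count.
#' @export
epoch_count <- function(n_samples, epoch_len = 1280L, hop = 640L) {
  n_samples <- as.numeric(n_samples)
  ifelse(n_samples < epoch_len, 0L,
         as.integer(floor((n_samples - epoch_len) / hop) + 1))
}

#' Epoch count implied by a printed dataset duration
#'
#' A corpus whose total duration counts each fixed-length epoch once
#' contains `duration_s / epoch_s` epochs.
#'
#' @param duration_s Total duration in seconds (or use `hours`/`minutes`/
#'   `seconds` parts).
#' @param epoch_s Epoch length in seconds (default 5).
#' @param hours,minutes,seconds Optional duration parts, summed into
#'   `duration_s` when it is missing.
#' @return Epoch count (numeric; integer-valued when the duration divides
#'   evenly).
#' @export
epochs_from_duration <- function(duration_s = NULL, epoch_s = 5,
                                 hours = 0, minutes = 0, seconds = 0) {
  if (is.null(duration_s)) duration_s <- hours * 3600 + minutes * 60 + seconds
  duration_s / epoch_s
}

#' Cut a 256 Hz recording into overlapping 5-second epochs
#'
#' Windows are half-open `[start, start + 1280)` with 0-based starts
#' 0, 640, 1280, ...; a trailing remainder shorter than one epoch is
#' discarded (fixed-size network input requires exactly 1280 samples).
#'
#' @param rec An `eeg_recording` at 256 Hz.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param overlap Fractional overlap between consecutive epochs (default 0.5).
#' @param on_short `"warn"` (default) or `"error"`: what to do when the
#'   recording is shorter than one epoch.
#' @return An `epoch_set`: list with `data` (array n x 19 x 1280) and
#'   `manifest` (data.frame with `subject_id`, `label`, `epoch`,
#'   `start_sample`).
#' @export
segment_epochs <- function(rec, epoch_s = 5, overlap = 0.5,
                           on_short = c("warn", "error")) {
  on_short <- match.arg(on_short)
  if (rec$fs != 256) {
    stop("segment_epochs expects a 256 Hz recording; call resample_recording first",
         call. = FALSE)
  }
  len <- as.integer(round(epoch_s * rec$fs))
  hop <- as.integer(round(len * (1 - overlap)))
  n <- ncol(rec$data)
  k <- epoch_count(n, len, hop)
  if (k == 0L) {
    msg <- sprintf("recording %s shorter than one epoch (%d < %d samples)",
                   rec$subject_id, n, len)
    if (on_short == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return(empty_epoch_set(len))
  }
  starts <- (seq_len(k) - 1L) * hop  # 0-based
  data <- array(0, dim = c(k, nrow(rec$data), len))
  for (i in seq_len(k)) {
    data[i, , ] <- rec$data[, (starts[i] + 1L):(starts[i] + len)]
  }
  manifest <- data.frame(subject_id = rec$subject_id, label = rec$label,
                         epoch = seq_len(k), start_sample = starts,
                         stringsAsFactors = FALSE)
  structure(list(data = data, manifest = manifest, fs = rec$fs),
            class = "epoch_set")
}

empty_epoch_set <- function(len = 1280L) {
  structure(list(data = array(0, dim = c(0, 19, len)),
                 manifest = data.frame(subject_id = character(0),
                                       label = character(0),
                                       epoch = integer(0),
                                       start_sample = integer(0),
                                       stringsAsFactors = FALSE),
                 fs = 256),
            class = "epoch_set")
}

#' Combine epoch sets from several recordings
#'
#' @param ... `epoch_set` objects (or a single list of them).
#' @return One `epoch_set` with rows concatenated in input order.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  sets <- Filter(function(s) nrow(s$manifest) > 0, sets)
  if (length(sets) == 0L) return(empty_epoch_set())
  len <- dim(sets[[1]]$data)[3]
  n <- sum(vapply(sets, function(s) dim(s$data)[1], integer(1)))
  data <- array(0, dim = c(n, dim(sets[[1]]$data)[2], len))
  off <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    if (k > 0) data[(off + 1L):(off + k), , ] <- s$data
    off <- off + k
  }
  manifest <- do.call(rbind, lapply(sets, `[[`, "manifest"))
  rownames(manifest) <- NULL
  structure(list(data = data, manifest = manifest, fs = sets[[1]]$fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples; %d subject(s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              length(unique(x$manifest$subject_id))))
  if (nrow(x$manifest) > 0) print(table(x$manifest$label))
  invisible(x)
}

#' Write / read an epoch set container
#'
#' Epoch sets are stored as an RDS container plus a plain-text CSV manifest
#' alongside (same path with extension `.csv`), so provenance is inspectable
#' without loading the array. The round trip is bit-exact.
#'
#' @param x An `epoch_set`.
#' @param path Path to an `.rds` file.
#' @return `write_epoch_set` returns `path` invisibly; `read_epoch_set`
#'   returns the `epoch_set`.
#' @export
write_epoch_set <- function(x, path) {
  saveRDS(x, path)
  utils::write.csv(x$manifest, sub("\\.rds$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "epoch_set")) stop("not an epoch_set container", call. = FALSE)
  x
}

#' Standard preprocessing: resample, filter, segment
#'
#' Applies the canonical preprocessing order — resample to 256 Hz first, then
#' band-pass 0.5-32 Hz, then cut 5-s epochs with 50% overlap.
#'
#' @param rec An `eeg_recording` at any rate.
#' @param low,high Band edges in Hz.
#' @inheritParams segment_epochs
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 32,
                                 epoch_s = 5, overlap = 0.5) {
  rec <- resample_recording(rec, 256)
  rec <- bandpass_recording(rec, low, high)
  segment_epochs(rec, epoch_s, overlap)
}
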