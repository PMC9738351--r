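# Minimal EDF/EDF+ support: 256-byte fixed header, 256 bytes per signal
# header, then data records of 16-bit little-endian integers scaled linearly
# between digital and physical ranges. Annotation channels ("EDF Annotations")
# are skipped on read. Continuous recordings only.

edf_field <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

#' Read an EDF/EDF+ file
#'
#' Reads all ordinary signals of a continuous EDF recording and returns them
#' as a channels x samples matrix in physical units. Signals must share one
#' sampling rate (the montage used here always does); annotation channels are
#' ignored.
#'
#' @param path Path to an `.edf` file.
#' @return List with `data` (channels x samples), `channel_names`, `fs`,
#'   and `meta` (header fields).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8L)
  if (version != "0") stop("format error: not an EDF file (version '", version, "')",
                           call. = FALSE)
  patient <- edf_field(con, 80L)
  recording <- edf_field(con, 80L)
  startdate <- edf_field(con, 8L)
  starttime <- edf_field(con, 8L)
  header_bytes <- as.integer(edf_field(con, 8L))
  reserved <- edf_field(con, 44L)
  n_records <- as.integer(edf_field(con, 8L))
  record_dur <- as.numeric(edf_field(con, 8L))
  ns <- as.integer(edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("format error: bad signal count", call. = FALSE)

  sig_field <- function(nchars) vapply(seq_len(ns), function(i) edf_field(con, nchars), "")
  labels <- sig_field(16L)
  transducer <- sig_field(80L)
  phys_dim <- sig_field(8L)
  phys_min <- as.numeric(sig_field(8L))
  phys_max <- as.numeric(sig_field(8L))
  dig_min <- as.numeric(sig_field(8L))
  dig_max <- as.numeric(sig_field(8L))
  prefilter <- sig_field(80L)
  spr <- as.integer(sig_field(8L))  # samples per record, per signal
  sig_field(32L)                    # per-signal reserved

  keep <- !grepl("^EDF Annotations", labels)
  if (!any(keep)) stop("format error: no data signals", call. = FALSE)
  if (length(unique(spr[keep])) != 1L) {
    stop("format error: signals have differing sampling rates", call. = FALSE)
  }
  fs <- spr[keep][1] / record_dur

  rec_len <- sum(spr)
  raw_all <- readBin(con, "integer", n = n_records * rec_len, size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_records * rec_len) {
    stop("format error: truncated EDF data", call. = FALSE)
  }
  dim(raw_all) <- c(rec_len, n_records)
  offsets <- cumsum(c(0L, spr))[seq_len(ns)]
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  kept <- which(keep)
  data <- matrix(0, length(kept), n_records * spr[kept[1]])
  for (j in seq_along(kept)) {
    s <- kept[j]
    dig <- as.vector(raw_all[(offsets[s] + 1L):(offsets[s] + spr[s]), ])
    data[j, ] <- (dig - dig_min[s]) * gain[s] + phys_min[s]
  }
  list(data = data, channel_names = labels[keep], fs = fs,
       meta = list(patient = patient, recording = recording,
                   startdate = startdate, starttime = starttime,
                   n_records = n_records, record_duration = record_dur,
                   phys_dim = phys_dim[keep]))
}

pad_field <- function(x, nchars) {
  x <- as.character(x)
  if (nchar(x) > nchars) x <- substr(x, 1L, nchars)
  formatC(x, width = -nchars)
}

#' Write an EDF file
#'
#' Writes a channels x samples matrix as a continuous EDF recording with
#' 1-second data records and a symmetric physical range wide enough for the
#' data. Used for fixtures, round-trip tests and exporting synthetic
#' recordings; quantization to the 16-bit digital range is the only loss.
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param channel_names Character vector, one name per row.
#' @param fs Sampling rate in Hz; `fs * 1` must be an integer (1-s records).
#' @param path Output path.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, channel_names, fs, path,
                      patient = "X", recording = "synthetic") {
  data <- as.matrix(data)
  ns <- nrow(data)
  if (length(channel_names) != ns) stop("one channel name per row required", call. = FALSE)
  if (fs != round(fs)) stop("fs must be an integer for 1-s records", call. = FALSE)
  spr <- as.integer(fs)
  n_records <- floor(ncol(data) / spr)
  if (n_records < 1L) stop("need at least one full 1-s record", call. = FALSE)
  used <- n_records * spr
  phys_absmax <- max(1, ceiling(max(abs(data[, seq_len(used), drop = FALSE]))))
  dig_min <- -32768; dig_max <- 32767
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, nchars) writeBin(charToRaw(pad_field(x, nchars)), con)
  wf("0", 8L)
  wf(patient, 80L)
  wf(recording, 80L)
  wf("01.01.26", 8L); wf("00.00.00", 8L)
  wf(header_bytes, 8L)
  wf("", 44L)
  wf(n_records, 8L)
  wf("1", 8L)
  wf(ns, 4L)
  for (nm in channel_names) wf(nm, 16L)
  for (i in seq_len(ns)) wf("", 80L)
  for (i in seq_len(ns)) wf("uV", 8L)
  for (i in seq_len(ns)) wf(-phys_absmax, 8L)
  for (i in seq_len(ns)) wf(phys_absmax, 8L)
  for (i in seq_len(ns)) wf(dig_min, 8L)
  for (i in seq_len(ns)) wf(dig_max, 8L)
  for (i in seq_len(ns)) wf("", 80L)
  for (i in seq_len(ns)) wf(spr, 8L)
  for (i in seq_len(ns)) wf("", 32L)

  gain <- (dig_max - dig_min) / (2 * phys_absmax)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] + phys_absmax) * gain + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
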