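#' Sifting configuration
#'
#' Controls the empirical-mode-decomposition sift loop. The stop criterion is
#' the classical Cauchy-type normalized squared difference between successive
#' sift iterates, `SD = sum((d_prev - d_new)^2) / sum(d_prev^2)`; sifting
#' stops once `SD < stop_threshold` and the candidate satisfies the
#' extrema/zero-crossing IMF condition, or after `max_sift_iterations`.
#'
#' @param stop_threshold Positive dimensionless threshold (default 0.2).
#' @param max_sift_iterations Cap on sift iterations per IMF (default 100).
#' @param max_imfs Number of IMFs to extract (default 3, the network input
#'   depth).
#' @param boundary_mode Envelope boundary handling; only `"mirror_extrema"`
#'   (reflect the two extrema nearest each end) is implemented.
#' @return A `sift_config` list.
#' @export
sift_config <- function(stop_threshold = 0.2, max_sift_iterations = 100L,
                        max_imfs = 3L, boundary_mode = "mirror_extrema") {
  stopifnot(stop_threshold > 0, max_sift_iterations >= 1, max_imfs >= 1)
  boundary_mode <- match.arg(boundary_mode, "mirror_extrema")
  structure(list(stop_threshold = stop_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 max_imfs = as.integer(max_imfs),
                 boundary_mode = boundary_mode),
            class = "sift_config")
}

#' Locate strict local extrema
#'
#' Extrema are sign changes of the first difference; a flat run (plateau) is
#' compressed to its midpoint and counted once, which keeps the IMF
#' extrema/zero-crossing count well defined on quantized signals. Endpoints
#' are never extrema.
#'
#' @param x Numeric vector, length >= 3.
#' @return List with `max_idx`, `max_val`, `min_idx`, `min_val`; indices are
#'   strictly increasing. Monotone input yields empty vectors.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max_idx = integer(0), max_val = numeric(0),
                          min_idx = integer(0), min_val = numeric(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) %/% 2L  # plateau midpoint
  v <- r$values
  m <- length(v)
  if (m < 3L) return(list(max_idx = integer(0), max_val = numeric(0),
                          min_idx = integer(0), min_val = numeric(0)))
  i <- 2:(m - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(max_idx = mid[i][is_max], max_val = v[i][is_max],
       min_idx = mid[i][is_min], min_val = v[i][is_min])
}

#' Count zero crossings
#'
#' Sign changes of the signal, with exact zeros transparent (a crossing is
#' counted once however many zero samples sit on it).
#'
#' @param x Numeric vector.
#' @return Integer count.
#' @export
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Does x satisfy IMF condition 1: |#extrema - #zero crossings| <= 1 ?
imf_condition_counts <- function(x) {
  e <- find_extrema(x)
  n_ext <- length(e$max_idx) + length(e$min_idx)
  abs(n_ext - count_zero_crossings(x)) <= 1L
}

# Natural cubic spline through the extrema of one polarity, after mirroring
# the two extrema nearest each end about the end samples. Returns the
# envelope sampled at 1..n, or NULL if fewer than 2 extrema exist.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  if (k < 2L) return(NULL)
  take <- seq_len(min(2L, k))
  left_pos <- 2L - idx[take]            # reflect about sample 1
  left_val <- val[take]
  rtake <- k + 1L - take                 # last, second-last
  right_pos <- 2L * n - idx[rtake]       # reflect about sample n
  right_val <- val[rtake]
  pos <- c(rev(left_pos), idx, right_pos)
  vv <- c(rev(left_val), val, right_val)
  keep <- !duplicated(pos)
  stats::spline(pos[keep], vv[keep], xout = seq_len(n), method = "natural")$y
}

# Internal envelope mean; NULL signals the monotone-residual condition.
envelope_mean_or_null <- function(x) {
  n <- length(x)
  e <- find_extrema(x)
  upper <- spline_envelope(e$max_idx, e$max_val, n)
  lower <- spline_envelope(e$min_idx, e$min_val, n)
  if (is.null(upper) || is.null(lower)) return(NULL)
  (upper + lower) / 2
}

#' Mean of the cubic-spline extrema envelopes
#'
#' Upper and lower envelopes are natural cubic splines through the local
#' maxima and minima respectively, with mirror extension of the two extrema
#' nearest each end; the local mean is their pointwise average. This is the
#' quantity the sift subtracts at each iteration.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @return Numeric vector `m(t)`, same length as `x`.
#' @export
envelope_mean <- function(x) {
  m <- envelope_mean_or_null(x)
  if (is.null(m)) {
    stop(monotone_residual_condition())
  }
  m
}

monotone_residual_condition <- function() {
  structure(class = c("emdnet_monotone_residual", "error", "condition"),
            list(message = "monotone residual: fewer than 2 maxima or 2 minima",
                 call = NULL))
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean from the working signal until the
#' candidate is an IMF: the normalized squared difference between successive
#' iterates falls below `cfg$stop_threshold` and the extrema/zero-crossing
#' counts differ by at most one, or `cfg$max_sift_iterations` is reached.
#' The residual returned is exactly `x - imf`.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @param cfg A [sift_config()].
#' @return List with `imf`, `residual`, `n_iterations`.
#' @export
sift_imf <- function(x, cfg = sift_config()) {
  d <- x
  m <- envelope_mean_or_null(d)
  if (is.null(m)) stop(monotone_residual_condition())
  it <- 0L
  repeat {
    it <- it + 1L
    d_new <- d - m
    sd_val <- sum(m^2) / sum(d^2)   # m = d - d_new
    d <- d_new
    if (it >= cfg$max_sift_iterations) break
    if (sd_val < cfg$stop_threshold && imf_condition_counts(d)) break
    m <- envelope_mean_or_null(d)
    if (is.null(m)) break  # over-sifted to monotone: accept current candidate
  }
  list(imf = d, residual = x - d, n_iterations = it)
}

#' Empirical mode decomposition
#'
#' Iteratively sifts IMFs from successive residuals until `cfg$max_imfs`
#' components are extracted or the residual has too few extrema to continue.
#' The components reconstruct the input: `rowSums of IMFs + residual == x`
#' holds exactly by construction (each residual is formed by subtraction).
#'
#' @param x Numeric vector (in pipeline use, one 1280-sample epoch channel).
#' @param cfg A [sift_config()].
#' @return An `imf_set`: list with `imfs` (length(x) x n matrix, possibly 0
#'   columns), `residual`, `n_imf`.
#' @export
emd_decompose <- function(x, cfg = sift_config()) {
  n <- length(x)
  imfs <- matrix(0, n, 0)
  r <- x
  for (k in seq_len(cfg$max_imfs)) {
    s <- tryCatch(sift_imf(r, cfg),
                  emdnet_monotone_residual = function(e) NULL)
    if (is.null(s)) break
    imfs <- cbind(imfs, s$imf)
    r <- s$residual
  }
  structure(list(imfs = imfs, residual = r, n_imf = ncol(imfs)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) of length %d\n", x$n_imf, length(x$residual)))
  invisible(x)
}

#' Local-orthogonality diagnostic for an IMF set
#'
#' Normalized inner products between all component pairs (IMFs and residual):
#' `<a,b> / sqrt(<a,a><b,b>)`. EMD components tend to be locally orthogonal
#' but this is a tendency, not a guarantee, so the value is reported as a
#' diagnostic only.
#'
#' @param dec An `imf_set`.
#' @return Symmetric matrix of normalized inner products (NA for zero-energy
#'   components).
#' @export
imf_orthogonality <- function(dec) {
  comps <- cbind(dec$imfs, dec$residual)
  k <- ncol(comps)
  out <- matrix(NA_real_, k, k)
  nrm <- sqrt(colSums(comps^2))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (nrm[i] > 0 && nrm[j] > 0) {
      out[i, j] <- sum(comps[, i] * comps[, j]) / (nrm[i] * nrm[j])
    }
  }
  labs <- c(if (dec$n_imf > 0) paste0("imf", seq_len(dec$n_imf)), "residual")
  dimnames(out) <- list(labs, labs)
  out
}

#' Build the network input tensor for one epoch
#'
#' Decomposes each of the 19 channels and stacks the first `max_imfs`
#' (default 3) IMFs into a channels x samples x IMF array. A channel that
#' yields fewer IMFs than requested has its missing planes zero-filled (with
#' a warning), so the tensor shape is always fixed.
#'
#' @param epoch_data 19 x 1280 numeric matrix (one epoch).
#' @param cfg A [sift_config()]; `max_imfs` fixes the tensor depth.
#' @return Numeric array 19 x 1280 x `max_imfs`.
#' @export
build_imf_tensor <- function(epoch_data, cfg = sift_config()) {
  epoch_data <- as.matrix(epoch_data)
  nc <- nrow(epoch_data); ns <- ncol(epoch_data)
  out <- array(0, dim = c(nc, ns, cfg$max_imfs))
  short <- integer(0)
  for (ch in seq_len(nc)) {
    dec <- emd_decompose(epoch_data[ch, ], cfg)
    k <- min(dec$n_imf, cfg$max_imfs)
    if (k > 0) out[ch, , seq_len(k)] <- dec$imfs[, seq_len(k)]
    if (dec$n_imf < cfg$max_imfs) short <- c(short, ch)
  }
  if (length(short) > 0) {
    warning("zero-filled missing IMF planes for channel(s): ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  out
}

#' Decompose every epoch of an epoch set
#'
#' Maps [build_imf_tensor()] over an `epoch_set`, producing the tensor stack
#' the classifier consumes.
#'
#' @param epochs An `epoch_set`.
#' @param cfg A [sift_config()].
#' @param verbose Print progress every 50 epochs.
#' @return An `imf_tensor_set`: list with `data` (array n x 19 x 1280 x
#'   `max_imfs`) and the epoch `manifest`.
#' @export
decompose_epochs <- function(epochs, cfg = sift_config(), verbose = FALSE) {
  n <- dim(epochs$data)[1]
  out <- array(0, dim = c(n, dim(epochs$data)[2], dim(epochs$data)[3],
                          cfg$max_imfs))
  for (i in seq_len(n)) {
    out[i, , , ] <- suppressWarnings(build_imf_tensor(epochs$data[i, , ], cfg))
    if (verbose && i %% 50L == 0L) message("decomposed ", i, "/", n, " epochs")
  }
  structure(list(data = out, manifest = epochs$manifest, cfg = cfg),
            class = "imf_tensor_set")
}

#' @export
print.imf_tensor_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<imf_tensor_set> %d tensors of %d x %d x %d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Write / read an IMF tensor container
#'
#' RDS container holding the tensor stack, integer class codes (ES=0, PNES=1,
#' CS=2) and subject IDs, with the manifest mirrored to CSV alongside.
#' Round trip is bit-exact.
#'
#' @param x An `imf_tensor_set`.
#' @param path Path to an `.rds` file.
#' @export
write_imf_tensors <- function(x, path) {
  saveRDS(x, path)
  utils::write.csv(x$manifest, sub("\\.rds$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_imf_tensors
#' @export
read_imf_tensors <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "imf_tensor_set")) stop("not an imf_tensor_set container", call. = FALSE)
  x
}
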