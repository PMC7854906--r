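# Band-pass filtering backend: Butterworth design via the signal package,
# zero-phase forward-backward application through the compiled kernel.

# Steady-state filter state for a unit step input (to be scaled by the
# first sample of each pass); suppresses start-up transients.
lfilter_zi <- function(b, a) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  b <- b / a[1]
  a <- a / a[1]
  # companion matrix of a, transposed
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Design a zero-phase Butterworth band-pass filter
#'
#' Order-4 (by default) Butterworth band-pass coefficients plus the
#' steady-state initial conditions used by the forward-backward
#' application, so the composite filter has zero phase and squared
#' magnitude response.
#'
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz; must exceed `2 * hi`.
#' @param order Butterworth prototype order (the band-pass filter has
#'   twice as many poles).
#' @return A `band_filter` object holding `b`, `a`, `zi` and the
#'   reflection padding length.
#' @export
design_band_filter <- function(lo, hi, fs, order = 4L) {
  if (fs <= 2 * hi)
    stop("band [", lo, ", ", hi, "] Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz")
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  structure(
    list(b = as.numeric(bt$b), a = as.numeric(bt$a),
         zi = lfilter_zi(as.numeric(bt$b), as.numeric(bt$a)),
         padlen = 3L * length(bt$b), lo = lo, hi = hi, fs = fs,
         order = order),
    class = "band_filter")
}

# Apply a band filter forward-backward to every column of a matrix.
apply_band_filter <- function(filt, x) {
  x <- as.matrix(x)
  if (nrow(x) <= filt$padlen)
    stop("series of length ", nrow(x), " too short for zero-phase ",
         "filtering (needs > ", filt$padlen, " samples)")
  cpp_filtfilt(filt$b, filt$a, x, filt$zi, filt$padlen)
}

#' Decompose windowed EEG into frequency bands
#'
#' Applies the zero-phase Butterworth band-pass bank to every window and
#' channel. Each window is filtered independently (windows are
#' self-contained units), so there is no group delay between bands and no
#' leakage across window boundaries.
#'
#' @param epochs an [epoched_eeg()] object.
#' @param bands list of [band_spec()]; defaults to the canonical five.
#' @param order Butterworth prototype order.
#' @return Array `[n_windows, n_channels, n_bands, n_samples]`.
#' @export
band_filter_bank <- function(epochs, bands = default_bands(), order = 4L) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  d <- dim(epochs$data)
  nw <- d[1]; nc <- d[2]; ns <- d[3]
  nb <- length(bands)
  out <- array(NA_real_, c(nw, nc, nb, ns))
  # one series per column: samples x (windows * channels)
  xm <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = ns)
  for (k in seq_len(nb)) {
    filt <- design_band_filter(bands[[k]]$lo, bands[[k]]$hi, epochs$fs, order)
    y <- apply_band_filter(filt, xm)
    out[, , k, ] <- aperm(array(y, c(ns, nw, nc)), c(2, 3, 1))
  }
  out
}
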