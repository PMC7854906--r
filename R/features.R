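#' Windowed multichannel EEG
#'
#' Container for segmented EEG: a `[n_windows, n_channels, n_samples]`
#' array with a sampling rate, one class label and one domain identifier
#' (recording day or subject) per window, and montage channel names.
#'
#' @param data numeric array `[n_windows, n_channels, n_samples]`.
#' @param fs sampling rate in Hz.
#' @param labels integer class label per window.
#' @param domains integer domain identifier per window.
#' @param channel_names character vector of montage labels, one per
#'   channel.
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, labels, domains, channel_names) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("data must be a 3-d array [windows, channels, samples]")
  nw <- dim(data)[1]
  labels <- as.integer(labels)
  domains <- as.integer(domains)
  if (length(labels) == 1L) labels <- rep(labels, nw)
  if (length(domains) == 1L) domains <- rep(domains, nw)
  if (length(labels) != nw || length(domains) != nw)
    stop("labels and domains must have one entry per window")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2])
    stop("channel_names must have one entry per channel")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  structure(
    list(data = data, fs = fs, labels = labels, domains = domains,
         channel_names = channel_names),
    class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_eeg> %d windows x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %s | domains: %s\n",
              paste(sort(unique(x$labels)), collapse = ","),
              paste(sort(unique(x$domains)), collapse = ",")))
  invisible(x)
}

#' Segment a continuous recording into overlapping windows
#'
#' Windows are left-aligned starting at sample 1 and advance by a fixed
#' hop of `(1 - overlap_frac) * window_s * fs` samples; a trailing partial
#' window is dropped. A 50-s recording cut into 2-s windows with 50%
#' overlap therefore yields 49 windows.
#'
#' @param signal numeric matrix `[n_channels, n_total]`.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 2 s).
#' @param overlap_frac fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param label,domain class label and domain identifier attached to every
#'   window of this recording.
#' @param channel_names montage labels; defaults to `rownames(signal)` or
#'   `ch1..chN`.
#' @return An [epoched_eeg()] object.
#' @export
segment_windows <- function(signal, fs, window_s = 2, overlap_frac = 0.5,
                            label = 1L, domain = 1L, channel_names = NULL) {
  signal <- as.matrix(signal)
  n_total <- ncol(signal)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  w <- window_s * fs
  if (abs(w - round(w)) > 1e-8)
    stop("window_s * fs = ", w, " is not an integer number of samples ",
         "(window_s = ", window_s, ", fs = ", fs, ")")
  w <- as.integer(round(w))
  h <- (1 - overlap_frac) * w
  if (abs(h - round(h)) > 1e-8)
    stop("hop (1 - overlap_frac) * window_s * fs = ", h,
         " is not an integer number of samples (overlap_frac = ",
         overlap_frac, ")")
  h <- as.integer(round(h))
  if (n_total < w)
    stop("signal (", n_total, " samples) is shorter than one window (",
         w, " samples)")
  n_win <- (n_total - w) %/% h + 1L
  starts <- (seq_len(n_win) - 1L) * h
  nc <- nrow(signal)
  data <- array(NA_real_, c(n_win, nc, w))
  for (i in seq_len(n_win))
    data[i, , ] <- signal[, (starts[i] + 1L):(starts[i] + w), drop = FALSE]
  if (is.null(channel_names)) {
    channel_names <- rownames(signal)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  }
  epoched_eeg(data, fs, label, domain, channel_names)
}

#' Differential entropy of a Gaussian signal
#'
#' For a Gaussian window with variance `sigma2` the differential entropy
#' has the closed form `0.5 * log(2 * pi * e * sigma2)` nats, which is the
#' per-band feature used throughout the pipeline.
#'
#' @param sigma2 variance(s), in squared signal units; must be
#'   non-negative.
#' @param var_floor lower clamp applied to degenerate (near-zero)
#'   variances so windows of constant signal give a finite feature; a
#'   warning is raised when the clamp engages.
#' @return Differential entropy in nats, same shape as `sigma2`.
#' @examples
#' differential_entropy(1 / (2 * pi * exp(1))) # exactly 0
#' differential_entropy(4) - differential_entropy(1) # log(2)
#' @export
differential_entropy <- function(sigma2, var_floor = 1e-12) {
  if (any(!is.finite(sigma2))) stop("variance must be finite")
  if (any(sigma2 < 0)) stop("variance must be non-negative")
  if (any(sigma2 < var_floor))
    warning("clamping ", sum(sigma2 < var_floor),
            " degenerate variance(s) at the floor ", var_floor)
  0.5 * log(2 * pi * exp(1) * pmax(sigma2, var_floor))
}

#' Extract per-band differential-entropy features
#'
#' For every window, channel and band, band-pass filters the window
#' (zero-phase Butterworth) and takes the differential entropy of the
#' resulting variance. The variance is the population variance (divide by
#' n): the feature is a per-window statistic, not an inferential estimate.
#'
#' @inheritParams band_filter_bank
#' @param var_floor passed to [differential_entropy()].
#' @param chunk number of window-channel series filtered per block (bounds
#'   peak memory on large datasets).
#' @return A `de_features` object: `values` `[n_windows, n_channels,
#'   n_bands]` in nats, plus `bands`, `labels`, `domains`,
#'   `channel_names`.
#' @export
extract_de_features <- function(epochs, bands = default_bands(),
                                order = 4L, var_floor = 1e-12,
                                chunk = 16384L) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  d <- dim(epochs$data)
  nw <- d[1]; nc <- d[2]; ns <- d[3]
  nb <- length(bands)
  xm <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = ns) # series per column
  values <- array(NA_real_, c(nw, nc, nb),
                  dimnames = list(NULL, epochs$channel_names,
                                  band_names(bands)))
  n_series <- ncol(xm)
  for (k in seq_len(nb)) {
    filt <- design_band_filter(bands[[k]]$lo, bands[[k]]$hi, epochs$fs, order)
    v <- numeric(n_series)
    for (from in seq(1L, n_series, by = chunk)) {
      to <- min(from + chunk - 1L, n_series)
      y <- apply_band_filter(filt, xm[, from:to, drop = FALSE])
      mu <- colMeans(y)
      v[from:to] <- colMeans(y * y) - mu * mu
    }
    values[, , k] <- differential_entropy(matrix(v, nrow = nw),
                                          var_floor = var_floor)
  }
  structure(
    list(values = values, bands = bands, labels = epochs$labels,
         domains = epochs$domains, channel_names = epochs$channel_names,
         fs = epochs$fs),
    class = "de_features")
}

#' @export
print.de_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<de_features> %d windows x %d channels x %d bands (nats)\n",
              d[1], d[2], d[3]))
  invisible(x)
}
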