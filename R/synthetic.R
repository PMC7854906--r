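# Synthetic band-structured EEG: classes differ in per-band, per-region
# signal power (what the DE features measure); domains differ by
# per-channel gain, DC offset and broadband noise level (what the
# adaptation has to undo). Band-limited components are synthesized by
# filtering white noise with the same filter bank the feature extractor
# uses, so generator and extractor agree exactly on band definitions.

#' Synthetic EEG specification
#'
#' @param n_channels number of electrodes (drawn from the packaged
#'   61-channel layout; at most 61).
#' @param fs sampling rate in Hz.
#' @param duration_s trial length in seconds (50 s gives the canonical 49
#'   windows at 2 s / 50% overlap).
#' @param n_trials trials per class per domain.
#' @param classes list of class effects; each a `[n_bands, 3]` multiplier
#'   matrix (rows = bands, columns = frontal/central/posterior regions)
#'   applied to the base band amplitudes. Scalars and vectors recycle.
#' @param domains list of domain effects; each a list with `offset` (DC,
#'   in signal units), `noise_mult` (broadband noise multiplier) and one
#'   of: an explicit per-channel `gain` vector, `gain_log_sd`
#'   (channel-independent log-normal gains) or `gain_spatial_sd` (a
#'   smooth low-order spatial gain field over the scalp with the given
#'   log-scale standard deviation across channels -- the harder shift,
#'   since it cannot be averaged out spatially and directly confounds
#'   regional band-power signatures).
#' @param base_amp per-band base component amplitude (standard deviation
#'   in signal units, e.g. microvolts), one per band.
#' @param noise_amp broadband (1-50 Hz wide) noise standard deviation.
#' @param bands band bank; defaults to the canonical five.
#' @param seed integer seed controlling gains and signals.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_channels = 61L, fs = 128, duration_s = 50,
                           n_trials = 6L,
                           classes = list(1, 1),
                           domains = list(list(gain_log_sd = 0,
                                               offset = 0, noise_mult = 1)),
                           base_amp = c(8, 6, 5, 3, 2),
                           noise_amp = 2,
                           bands = default_bands(), seed = 1L) {
  nb <- length(bands)
  classes <- lapply(classes, function(m) {
    m <- matrix(as.numeric(m), nb, 3L)
    if (any(m <= 0)) stop("class multipliers must be positive")
    m
  })
  domains <- lapply(domains, function(d) {
    d$offset <- d[["offset"]] %||% 0
    d$noise_mult <- d[["noise_mult"]] %||% 1
    if (is.null(d[["gain"]]) && is.null(d[["gain_log_sd"]]) &&
        is.null(d[["gain_spatial_sd"]]))
      d$gain_log_sd <- 0
    d
  })
  if (!length(classes) || !length(domains))
    stop("need at least one class and one domain")
  if (length(base_amp) != nb)
    stop("base_amp must have one entry per band")
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         duration_s = duration_s, n_trials = as.integer(n_trials),
         classes = classes, domains = domains, base_amp = base_amp,
         noise_amp = noise_amp, bands = bands, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# frontal / central / posterior assignment from the montage geometry
#' Map montage channels to scalp regions
#'
#' Assigns every channel to exactly one of frontal, central or posterior
#' by the anterior-posterior coordinate of its 3-d position.
#'
#' @param m a [montage()] object.
#' @return Integer vector (1 = frontal, 2 = central, 3 = posterior) with
#'   region names as an attribute.
#' @export
channel_regions <- function(m) {
  y <- m$pos3d[, 2]
  r <- ifelse(y > 0.2, 1L, ifelse(y < -0.2, 3L, 2L))
  structure(as.integer(r), names = m$names,
            regions = c("frontal", "central", "posterior"))
}

# variance gain of each band filter for unit white noise (so components
# can be scaled to a target standard deviation)
.band_gains <- function(bands, fs, n = 2048L) {
  vapply(bands, function(b) {
    filt <- design_band_filter(b$lo, b$hi, fs)
    imp <- numeric(n); imp[n %/% 2] <- 1
    sum(apply_band_filter(filt, matrix(imp))^2)
  }, numeric(1))
}

#' Generate synthetic multichannel EEG trials
#'
#' Each trial is a sum of band-limited Gaussian components whose
#' per-channel standard deviation is `base_amp[band] *
#' class_multiplier[band, region(channel)]`, plus a domain DC offset and
#' domain-scaled broadband noise; the domain's per-channel gain
#' multiplies the complete signal last. Identical seeds give
#' bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param m optional [montage()]; defaults to the packaged layout,
#'   truncated to `spec$n_channels`.
#' @return A `synthetic_eeg` list: `trials` `[n_trials_total, n_channels,
#'   n_samples]`, `labels`, `domains`, `montage`, `gains` (per-domain
#'   channel gains) and the spec.
#' @export
generate_synthetic_eeg <- function(spec, m = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(m)) m <- packaged_montage()
  if (spec$n_channels > length(m$names))
    stop("n_channels (", spec$n_channels, ") exceeds montage size (",
         length(m$names), ")")
  keep <- seq_len(spec$n_channels)
  m <- montage(m$names[keep], m$pos3d[keep, , drop = FALSE])
  region <- channel_regions(m)
  nc <- spec$n_channels
  ns <- as.integer(round(spec$duration_s * spec$fs))
  nb <- length(spec$bands)
  n_cls <- length(spec$classes); n_dom <- length(spec$domains)
  n_total <- n_cls * n_dom * spec$n_trials
  set.seed(spec$seed)
  gains <- lapply(spec$domains, function(d) {
    if (!is.null(d[["gain"]])) {
      rep_len(as.numeric(d[["gain"]]), nc)
    } else if (!is.null(d[["gain_spatial_sd"]])) {
      # smooth linear field over the scalp, unit sd across channels
      pat <- as.numeric(m$pos3d %*% rnorm(3))
      pat <- (pat - mean(pat)) / max(stats::sd(pat), 1e-12)
      exp(d[["gain_spatial_sd"]] * pat)
    } else {
      exp(rnorm(nc, sd = d[["gain_log_sd"]]))
    }
  })
  filters <- lapply(spec$bands, function(b)
    design_band_filter(b$lo, b$hi, spec$fs))
  bgain <- .band_gains(spec$bands, spec$fs)
  broad <- design_band_filter(1, min(50, spec$fs / 2 - 1), spec$fs)
  broad_gain <- .band_gains(list(band_spec("broad", 1,
                                           min(50, spec$fs / 2 - 1))),
                            spec$fs)
  trials <- array(0, c(n_total, nc, ns))
  labels <- integer(n_total); doms <- integer(n_total)
  i <- 0L
  for (d in seq_len(n_dom)) for (cl in seq_len(n_cls)) {
    mult <- spec$classes[[cl]]
    for (tr in seq_len(spec$n_trials)) {
      i <- i + 1L
      sig <- matrix(0, ns, nc)
      for (b in seq_len(nb)) {
        comp <- apply_band_filter(filters[[b]], matrix(rnorm(ns * nc), ns, nc))
        amp <- spec$base_amp[b] * mult[b, region] / sqrt(bgain[b])
        sig <- sig + sweep(comp, 2, amp, "*")
      }
      de <- spec$domains[[d]]
      noise <- apply_band_filter(broad, matrix(rnorm(ns * nc), ns, nc)) /
        sqrt(broad_gain)
      sig <- sig + de$noise_mult * spec$noise_amp * noise + de$offset
      sig <- sweep(sig, 2, gains[[d]], "*")
      trials[i, , ] <- t(sig)
      labels[i] <- cl; doms[i] <- d
    }
  }
  structure(
    list(trials = trials, labels = labels, domains = doms, montage = m,
         gains = gains, spec = spec),
    class = "synthetic_eeg")
}

#' @export
print.synthetic_eeg <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<synthetic_eeg> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$spec$fs))
  invisible(x)
}

#' Window synthetic trials into an epoched set
#'
#' @param gen a `synthetic_eeg` from [generate_synthetic_eeg()].
#' @param window_s,overlap_frac see [segment_windows()].
#' @return An [epoched_eeg()] with per-window labels and domains.
#' @export
synthetic_epochs <- function(gen, window_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(gen, "synthetic_eeg"))
  pieces <- lapply(seq_len(dim(gen$trials)[1]), function(i)
    segment_windows(gen$trials[i, , ], gen$spec$fs, window_s, overlap_frac,
                    label = gen$labels[i], domain = gen$domains[i],
                    channel_names = gen$montage$names))
  data <- do.call(abind_windows, lapply(pieces, `[[`, "data"))
  epoched_eeg(data, gen$spec$fs,
              unlist(lapply(pieces, `[[`, "labels")),
              unlist(lapply(pieces, `[[`, "domains")),
              gen$montage$names)
}

# bind [n, c, s] arrays along the window axis
abind_windows <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' Packaged synthetic transfer benchmark
#'
#' A pinned two-class, three-domain, 61-channel dataset (50-s trials, so
#' each trial yields 49 windows at the default segmentation; 6 trials per
#' class per domain, i.e. 588 windows per domain). `easy` has a large
#' class separation (posterior Alpha and frontal Beta power) and a domain
#' shift (per-channel gain spread plus noise-level drift) strong enough
#' to visibly degrade a source-only classifier while leaving the
#' class-conditional band-power ratios intact for the adaptation to
#' exploit; `hard` shrinks the separation and strengthens the shift.
#'
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed integer seed.
#' @return A `synthetic_eeg` object (see [generate_synthetic_eeg()]).
#' @export
benchmark_fixture <- function(difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  nb <- 5L
  base <- matrix(1, nb, 3)
  cls2 <- base
  if (difficulty == "easy") {
    cls2[3, 3] <- 1.6   # Alpha, posterior
    cls2[4, 1] <- 1.4   # Beta, frontal
    cls2[2, 2] <- 0.7   # Theta, central
    domains <- list(
      list(gain_spatial_sd = 0.8, offset = 0, noise_mult = 1.0),
      list(gain_spatial_sd = 0.8, offset = 4, noise_mult = 2.2),
      list(gain_spatial_sd = 0.8, offset = -4, noise_mult = 3.5))
  } else {
    cls2[3, 3] <- 1.25
    cls2[4, 1] <- 1.15
    domains <- list(
      list(gain_spatial_sd = 1.1, offset = 0, noise_mult = 1.0),
      list(gain_spatial_sd = 1.1, offset = 6, noise_mult = 2.8),
      list(gain_spatial_sd = 1.1, offset = -6, noise_mult = 4.5))
  }
  spec <- synthetic_spec(
    n_channels = 61L, fs = 128, duration_s = 50, n_trials = 6L,
    classes = list(base, cls2), domains = domains, seed = seed)
  generate_synthetic_eeg(spec)
}

#' Run the image pipeline on a synthetic set
#'
#' Windows the trials, extracts differential-entropy features, renders
#' min-max standardized 32 x 32 x 5 images and returns the network-ready
#' dataset.
#'
#' @param gen a `synthetic_eeg`.
#' @param resolution image side length (default 32).
#' @param scope standardization scope, see [minmax_standardize()].
#' @return An `image_dataset` (see [as_image_dataset()]).
#' @export
prepare_image_dataset <- function(gen, resolution = 32L,
                                  scope = "per_image_band") {
  ep <- synthetic_epochs(gen)
  feats <- extract_de_features(ep, gen$spec$bands)
  imgs <- render_image_stack(feats, gen$montage, resolution = resolution)
  as_image_dataset(minmax_standardize(imgs, scope = scope))
}
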