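test_that("window counts match brute-force enumeration of start offsets", {
  # canonical recording protocol: 50 s, 2 s windows, 50% overlap -> 49 windows
  sig <- matrix(rnorm(128 * 50), 1)
  ep <- segment_windows(sig, 128, 2, 0.5)
  expect_equal(dim(ep$data)[1], 49L)
  # boundary: signal of exactly one window
  expect_equal(dim(segment_windows(matrix(rnorm(256), 1), 128, 2, 0.5)$data)[1],
               1L)
  # 5 s at 100 Hz: starts 0, 100, 200, 300 (brute-force enumerated)
  sig <- matrix(seq_len(500), 1)
  ep <- segment_windows(sig, 100, 2, 0.5)
  expect_equal(dim(ep$data)[1], 4L)
  for (i in 1:4)
    expect_equal(as.numeric(ep$data[i, 1, ]),
                 as.numeric(sig[1, ((i - 1) * 100 + 1):((i - 1) * 100 + 200)]))
  # randomized property: formula equals enumeration
  set.seed(42)
  for (rep in 1:40) {
    w <- sample(5:40, 1)
    h <- sample(1:w, 1)
    n <- w + sample(0:200, 1)
    ov <- 1 - h / w
    ep <- segment_windows(matrix(rnorm(n), 1), 1, w, ov)
    expect_equal(dim(ep$data)[1], count_windows_brute(n, w, h))
  }
})

test_that("segmentation rejects invalid windows with informative errors", {
  expect_error(segment_windows(matrix(rnorm(100), 1), 128, 2, 0.5),
               "shorter than one window")
  expect_error(segment_windows(matrix(rnorm(500), 1), 100, 1.505, 0.5),
               "not an integer")
  expect_error(segment_windows(matrix(rnorm(500), 1), 100, 2, 0.503),
               "not an integer")
  expect_error(segment_windows(matrix(rnorm(500), 1), 100, 2, 1.2),
               "overlap_frac")
})

test_that("band filters isolate their bands and reject ones above Nyquist", {
  fs <- 128
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ep <- segment_windows(matrix(sin(2 * pi * 10 * t), 1), fs, 2, 0)
  bank <- band_filter_bank(ep)
  v_in <- var(sin(2 * pi * 10 * t))
  v_bands <- apply(bank[1, 1, , ], 1, var)
  expect_gt(v_bands[3] / v_in, 0.90)  # Alpha retains the 10 Hz tone
  expect_lt(v_bands[1] / v_in, 0.01)  # Delta rejects it
  # linearity: zero in, zero out
  ep0 <- segment_windows(matrix(0, 1, 256), fs, 2, 0)
  expect_equal(max(abs(band_filter_bank(ep0))), 0)
  expect_error(design_band_filter(31, 70, fs), "Nyquist")
})

test_that("white-noise variance partition matches the frequency-response oracle", {
  # oracle: forward-backward filtering applies |H|^2, so the variance of
  # filtered unit white noise is mean(|H|^4) over frequencies; the
  # canonical bands leave 1-Hz gaps, so the five bands recover ~86% of
  # the 1-50 Hz band's variance rather than all of it
  fs <- 128
  freqs <- seq(0, fs / 2, length.out = 8001)
  h4 <- function(filt)
    Mod(signal::freqz(filt$b, filt$a, W = freqs * 2 * pi / fs)$h)^4
  num <- 0
  for (b in default_bands())
    num <- num + h4(design_band_filter(b$lo, b$hi, fs))
  den <- h4(design_band_filter(1, 50, fs))
  expected_ratio <- sum(num) / sum(den)
  set.seed(3)
  ep <- segment_windows(matrix(rnorm(fs * 8), 1), fs, 8, 0)
  bank <- band_filter_bank(ep)
  v_sum <- sum(apply(bank[1, 1, , ], 1, var))
  f15 <- design_band_filter(1, 50, fs)
  v_ref <- as.numeric(var(tdann:::apply_band_filter(f15,
                                                    matrix(ep$data[1, 1, ]))))
  expect_equal(v_sum / v_ref, expected_ratio, tolerance = 0.1)
})

test_that("differential entropy matches Gaussian quadrature across 7 decades", {
  s2 <- 10^seq(-3, 3, length.out = 31)
  expect_equal(differential_entropy(s2), de_quadrature(s2), tolerance = 1e-6)
  expect_equal(differential_entropy(1 / (2 * pi * exp(1))), 0)
  # quadrupling the variance adds exactly log(2)
  expect_equal(differential_entropy(4 * s2) - differential_entropy(s2),
               rep(log(2), length(s2)))
  # monotone in variance
  expect_true(all(diff(differential_entropy(s2)) > 0))
  expect_error(differential_entropy(-1), "non-negative")
  expect_warning(differential_entropy(0), "clamping")
})

test_that("DE feature extraction honors shape, band ordering and determinism", {
  fs <- 128
  set.seed(9)
  nw <- 6; nc <- 4
  sig <- matrix(rnorm(fs * 10 * nc), nc)
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  sig[2, ] <- sig[2, ] + 5 * sin(2 * pi * 10 * t) # alpha-dominant channel
  ep <- segment_windows(sig, fs, 2, 0.5)
  de <- extract_de_features(ep)
  expect_equal(dim(de$values), c(9L, nc, 5L))
  expect_true(all(is.finite(de$values)))
  # alpha DE beats delta DE on the 10 Hz channel (band-variance oracle)
  expect_true(all(de$values[, 2, 3] > de$values[, 2, 1]))
  # determinism: identical windows give identical rows
  ep2 <- ep
  ep2$data[2, , ] <- ep2$data[1, , ]
  de2 <- extract_de_features(ep2)
  expect_identical(de2$values[1, , ], de2$values[2, , ])
  # shift invariance of the variance-based feature (up to roundoff from
  # filtering the offset signal)
  ep3 <- ep
  ep3$data <- ep3$data + 100
  de3 <- extract_de_features(ep3)
  expect_lt(max(abs(de3$values - de$values)), 1e-4)
  # permutation equivariance over windows
  perm <- sample(dim(ep$data)[1])
  ep4 <- epoched_eeg(ep$data[perm, , , drop = FALSE], fs, ep$labels[perm],
                     ep$domains[perm], ep$channel_names)
  de4 <- extract_de_features(ep4)
  expect_equal(de4$values, de$values[perm, , ], tolerance = 1e-12)
})
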