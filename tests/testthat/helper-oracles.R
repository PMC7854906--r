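# Independent oracles used across the suite.

# Gaussian differential entropy by numerical quadrature of -int p log p.
de_quadrature <- function(sigma2) {
  vapply(sigma2, function(s2) {
    integrand <- function(x) {
      p <- stats::dnorm(x, sd = sqrt(s2))
      ifelse(p > 0, -p * log(p), 0)
    }
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Explicit O(n^2) double-sum squared-MMD estimator.
mmd2_double_sum <- function(fs, ft, bank, cc = 2) {
  kv <- function(x, y) {
    d2 <- sum((x - y)^2)
    sum(bank$weights * exp(-d2 / (2 * bank$sigmas)))
  }
  ns <- nrow(fs); nt <- nrow(ft)
  s <- 0
  for (i in 1:ns) for (j in 1:ns) s <- s + kv(fs[i, ], fs[j, ])
  st <- 0
  for (i in 1:ns) for (j in 1:nt) st <- st + kv(fs[i, ], ft[j, ])
  tt <- 0
  for (i in 1:nt) for (j in 1:nt) tt <- tt + kv(ft[i, ], ft[j, ])
  s / ns^2 - cc * st / (ns * nt) + tt / nt^2
}

# brute-force count of valid left-aligned window start offsets
count_windows_brute <- function(n_total, w, h) {
  starts <- seq(0, n_total, by = h)
  sum(starts + w <= n_total)
}

# bind two [n, bands, H, W] stacks along the sample axis
abind_test <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# small labelled multi-domain image dataset for training tests
tiny_benchmark <- function(seed = 7, n_domains = 2, n_trials = 1,
                           duration_s = 30, n_channels = 16,
                           shift = TRUE) {
  base <- matrix(1, 5, 3)
  cls2 <- base
  cls2[3, 3] <- 1.8
  cls2[4, 1] <- 1.5
  doms <- lapply(seq_len(n_domains), function(d)
    if (shift)
      list(gain_spatial_sd = 0.6, offset = 2 * (d - 1),
           noise_mult = 1 + 0.8 * (d - 1))
    else list(gain_log_sd = 0, offset = 0, noise_mult = 1))
  spec <- synthetic_spec(
    n_channels = n_channels, fs = 128, duration_s = duration_s,
    n_trials = n_trials, classes = list(base, cls2), domains = doms,
    seed = seed)
  prepare_image_dataset(generate_synthetic_eeg(spec))
}

# fast config for training tests
tiny_config <- function(...) {
  dots <- list(...)
  base <- list(batch_source = 20L, batch_target = 20L, max_epochs = 2L,
               patience = 2L, seed = 5L)
  do.call(adaptation_config, utils::modifyList(base, dots))
}
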