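test_that("classification loss matches hand-computed cross-entropies", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(classification_loss(onehot, 1:3), 0, tolerance = 1e-10)
  uni <- matrix(1 / 4, 5, 4)
  expect_equal(classification_loss(uni, rep(2, 5)), log(4))
  # invariance under sample reordering
  set.seed(1)
  p <- t(apply(matrix(runif(40), 10), 1, function(r) r / sum(r)))
  y <- sample(1:4, 10, replace = TRUE)
  perm <- sample(10)
  expect_equal(classification_loss(p, y),
               classification_loss(p[perm, ], y[perm]))
  expect_error(classification_loss(p, c(y[-1], 9)), "out of range")
})

test_that("multi-kernel evaluations match the closed form", {
  b1 <- kernel_bank(1)
  expect_equal(mk_kernel(c(0, 0), c(0, 0), b1), 1)
  expect_equal(mk_kernel(0, 1, b1), exp(-0.5), tolerance = 1e-12)
  # strictly decreasing in squared distance
  d <- seq(0, 3, by = 0.25)
  v <- vapply(d, function(x) mk_kernel(0, x, b1), numeric(1))
  expect_true(all(diff(v) < 0))
  # normalized weights: k(x, x) = 1 for any bank
  bk <- kernel_bank(c(0.5, 1, 2), c(2, 3, 5))
  expect_equal(mk_kernel(1:4, 1:4, bk), 1)
  expect_error(kernel_bank(c(1, -1)), "positive")
})

test_that("mmd2 equals the explicit double-sum oracle to 1e-10", {
  set.seed(10)
  for (rep in 1:25) {
    ns <- sample(1:50, 1); nt <- sample(1:50, 1); d <- sample(1:5, 1)
    fs <- matrix(rnorm(ns * d), ns)
    ft <- matrix(rnorm(nt * d, mean = runif(1, -1, 1)), nt)
    bank <- kernel_bank(runif(3, 0.2, 4))
    for (cc in c(1, 2))
      expect_equal(mmd2(fs, ft, bank, cc), mmd2_double_sum(fs, ft, bank, cc),
                   tolerance = 1e-10)
  }
  # closed-form singleton cases, single kernel sigma = 1
  b1 <- kernel_bank(1)
  expect_equal(mmd2(0, 1, b1), 2 - 2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(mmd2(0, 2, b1), 2 - 2 * exp(-2), tolerance = 1e-12)
  # identical samples -> 0 under the default coefficient
  x <- matrix(rnorm(30), 10)
  expect_lt(abs(mmd2(x, x, b1)), 1e-9)
})

test_that("default mmd2 is nonnegative and grows with the mean shift", {
  set.seed(20)
  bank <- kernel_bank(c(0.5, 1, 2))
  for (rep in 1:30) {
    fs <- matrix(rnorm(40), 20)
    ft <- matrix(rnorm(40, mean = runif(1, -2, 2)), 20)
    expect_gte(mmd2(fs, ft, bank), -1e-9)
  }
  mus <- c(0, 0.5, 1, 2)
  avg <- sapply(mus, function(mu) {
    mean(sapply(1:8, function(s) {
      set.seed(100 + s)
      mmd2(matrix(rnorm(100), 50), matrix(rnorm(100, mu), 50), bank)
    }))
  })
  expect_true(all(diff(avg) > 0))
})

test_that("mmd2 gradients agree with finite differences", {
  set.seed(30)
  fs <- matrix(rnorm(12), 4); ft <- matrix(rnorm(9), 3)
  bank <- kernel_bank(c(0.7, 2))
  g <- tdann:::.mmd2_grad(fs, ft, bank, 2)
  eps <- 1e-6
  for (k in 1:5) {
    i <- sample(length(fs), 1)
    fp <- fs; fp[i] <- fp[i] + eps
    fm <- fs; fm[i] <- fm[i] - eps
    num <- (mmd2(fp, ft, bank) - mmd2(fm, ft, bank)) / (2 * eps)
    expect_equal(g$source[i], num, tolerance = 1e-5)
  }
  i <- sample(length(ft), 1)
  fp <- ft; fp[i] <- fp[i] + eps
  fm <- ft; fm[i] <- fm[i] - eps
  expect_equal(g$target[i],
               (mmd2(fs, fp, bank) - mmd2(fs, fm, bank)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("median-heuristic bank is centered, spaced and scales correctly", {
  b <- median_heuristic_bank(matrix(0, 1, 2), matrix(c(2, 0), 1), 1)
  expect_equal(b$sigmas, 4) # single pair at squared distance 4
  set.seed(5)
  fs <- matrix(rnorm(20), 10); ft <- matrix(rnorm(20), 10)
  b5 <- median_heuristic_bank(fs, ft, 5, 2)
  med <- median(dist(rbind(fs, ft))^2)
  expect_equal(b5$sigmas / med, c(1 / 4, 1 / 2, 1, 2, 4))
  expect_equal(b5$weights, rep(0.2, 5))
  a <- 3
  ba <- median_heuristic_bank(a * fs, a * ft, 5, 2)
  expect_equal(ba$sigmas, a^2 * b5$sigmas)
  expect_error(median_heuristic_bank(matrix(1, 2, 2), matrix(1, 2, 2)),
               "identical")
})

test_that("domain cross-entropy follows the stated sign conventions", {
  uni <- matrix(0.5, 6, 2)
  expect_equal(domain_adversarial_loss(uni, rep(1:2, 3)), log(2))
  sure <- rbind(c(1, 0), c(0, 1))
  expect_equal(domain_adversarial_loss(sure, 1:2), 0, tolerance = 1e-10)
  # relabeling symmetry: swapping labels with score columns
  set.seed(2)
  p <- t(apply(matrix(runif(20), 10), 1, function(r) r / sum(r)))
  y <- sample(1:2, 10, replace = TRUE)
  expect_equal(domain_adversarial_loss(p, y),
               domain_adversarial_loss(p[, 2:1], 3L - y))
})

test_that("gradient penalty uses exact input gradients", {
  set.seed(3)
  pts <- matrix(rnorm(40), 10)
  # unit-slope linear discriminator -> zero penalty
  w <- rnorm(4); w <- w / sqrt(sum(w^2))
  lin <- list(grad = function(x) matrix(w, nrow(x), 4, byrow = TRUE))
  expect_equal(gradient_penalty(lin, pts), 0, tolerance = 1e-12)
  # s(x) = 2x in one dimension -> (2 - 1)^2 = 1
  two <- list(grad = function(x) matrix(2, nrow(x), 1))
  expect_equal(gradient_penalty(two, matrix(rnorm(5))), 1)
  # constant discriminator -> (0 - 1)^2 = 1
  const <- list(grad = function(x) matrix(0, nrow(x), ncol(x)))
  expect_equal(gradient_penalty(const, pts), 1)
  # quadratic s(x) = x' A x: grad = (A + A') x, hand-computed
  A <- matrix(rnorm(16), 4)
  quad <- list(grad = function(x) x %*% (A + t(A)))
  norms <- sqrt(rowSums((pts %*% (A + t(A)))^2))
  expect_equal(gradient_penalty(quad, pts), mean((norms - 1)^2),
               tolerance = 1e-8)
  expect_error(gradient_penalty(list(), pts), "gradient")
})

test_that("combined objectives are the stated linear combinations", {
  # L_C=1, H=0.6, L_MMD=0.2, ||W||^2=10, lambdas (0.1, 0.1, 0.01)
  expect_equal(generator_objective(1, 0.6, 0.2, 10, 0.1, 0.1, 0.01), 1.06)
  expect_equal(generator_objective(1.3, 0.5, 0.4, 2, 0, 0, 0), 1.3)
  # linearity: d L_G / d lambda_m = L_MMD
  eps <- 1e-6
  expect_equal((generator_objective(1, 0.6, 0.2, 10, 0.1, 0.1 + eps, 0.01) -
                generator_objective(1, 0.6, 0.2, 10, 0.1, 0.1, 0.01)) / eps,
               0.2, tolerance = 1e-6)
  expect_equal(discriminator_objective(log(2), 1, 10), log(2) + 10)
  expect_equal(discriminator_objective(0.4, 0.3, 0), 0.4)
  expect_gte(discriminator_objective(0.7, 0.2, 5), 0)
})
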