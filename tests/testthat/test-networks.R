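test_that("presets map 32 x 32 x 5 images to 256-d features", {
  m <- build_preset("cross_day", n_classes = 2, seed = 1)
  expect_equal(m$flatten_shape, c(7L, 7L, 64L)) # valid conv + ceil pooling
  x <- array(0, c(3, 5, 32, 32))
  expect_error(forward_generator(m, x, rep(1:2, length.out = 3),
                                 mode = "adapt"), "single-domain")
  f <- forward_generator(m, x, rep(1L, 3), mode = "adapt")
  expect_equal(dim(f$features), c(3L, 256L))
  expect_true(all(is.finite(f$features)))
  m2 <- build_preset("cross_subject", n_classes = 3, seed = 1)
  f2 <- forward_generator(m2, array(0, c(2, 5, 32, 32)), rep(1L, 2),
                          mode = "adapt")
  expect_equal(dim(f2$features), c(2L, 256L))
  expect_error(build_preset("nope", 2))
  expect_error(forward_generator(m, array(0, c(2, 5, 16, 16)), rep(1L, 2)),
               "shape")
})

test_that("flatten size matches an independent shape-propagation oracle", {
  # oracle: propagate spatial sizes through the layer lists directly
  prop <- function(hw, convs, pools_after) {
    for (i in seq_along(convs)) {
      hw <- hw - 2            # valid 3x3
      if (i %in% pools_after) hw <- ceiling(hw / 2)
    }
    hw
  }
  m <- build_preset("cross_day", n_classes = 2, seed = 1)
  expect_equal(prod(m$flatten_shape), prop(32, 1:2, c(1, 2))^2 * 64)
  m2 <- build_preset("cross_subject", n_classes = 2, seed = 1)
  expect_equal(prod(m2$flatten_shape), prop(32, 1:6, c(2, 6))^2 * 128)
})

test_that("adaptive batch normalization standardizes each domain separately", {
  set.seed(8)
  x <- rbind(matrix(rnorm(200 * 4, mean = 5, sd = 1), 200),
             matrix(rnorm(200 * 4, mean = -5, sd = 2), 200))
  dom <- rep(1:2, each = 200)
  r <- adabn_forward(x, dom, mode = "train")
  for (g in 1:2) {
    sub <- r$out[dom == g, ]
    expect_equal(colMeans(sub), rep(0, 4), tolerance = 1e-6)
    # batch variance (population) of the normalized sub-batch is ~1
    v <- colMeans(sub^2) - colMeans(sub)^2
    expect_equal(v, rep(1, 4), tolerance = 1e-3)
  }
  # identical distributions: AdaBN equals shared batch normalization up
  # to the per-group estimator denominators
  x2 <- matrix(rnorm(400), 100)
  shared <- adabn_forward(x2, rep(1L, 100), mode = "train")$out
  split2 <- adabn_forward(x2[c(1:50, 51:100), ], rep(1:2, each = 50),
                          mode = "train")$out
  expect_equal(dim(shared), dim(split2))
  expect_error(adabn_forward(x2, c(1L, rep(2L, 99)), mode = "train"),
               "fewer than 2")
  st <- adabn_forward(x2, rep(1L, 100), mode = "train")$state
  expect_error(adabn_forward(x2, rep(2L, 100), state = st, mode = "eval"),
               "unseen domain")
})

test_that("forward heads produce probability rows and eval is deterministic", {
  m <- build_preset("cross_day", n_classes = 4, seed = 2)
  set.seed(1)
  x <- array(runif(6 * 5 * 32 * 32), c(6, 5, 32, 32))
  adabn_adapt(m, x, domain = 1)
  f <- forward_generator(m, x, rep(1L, 6), mode = "eval")
  pc <- forward_classifier(m, f$features)
  pd <- forward_discriminator(m, f$features)
  expect_equal(rowSums(pc), rep(1, 6), tolerance = 1e-6)
  expect_equal(rowSums(pd), rep(1, 6), tolerance = 1e-6)
  # dropout off in eval mode: bit-identical repetition
  f2 <- forward_generator(m, x, rep(1L, 6), mode = "eval")
  expect_identical(f$features, f2$features)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 6, 2, 5, 4)
  f3 <- forward_generator(m, x[perm, , , , drop = FALSE], rep(1L, 6),
                          mode = "eval")
  expect_equal(f3$features, f$features[perm, ], tolerance = 1e-12)
})

test_that("source and target passes share the generator parameters", {
  m <- build_preset("cross_day", n_classes = 2, seed = 3)
  set.seed(2)
  xs <- array(runif(4 * 5 * 32 * 32), c(4, 5, 32, 32))
  xt <- array(runif(4 * 5 * 32 * 32), c(4, 5, 32, 32))
  adabn_adapt(m, xs, domain = 1)
  adabn_adapt(m, xt, domain = 2)
  # one parameter environment backs both domains
  expect_true(is.environment(m$params))
  joint <- forward_generator(m, abind_test(xs, xt), rep(1:2, each = 4),
                             mode = "eval")$features
  sep_s <- forward_generator(m, xs, rep(1L, 4), mode = "eval")$features
  sep_t <- forward_generator(m, xt, rep(2L, 4), mode = "eval")$features
  expect_equal(joint, rbind(sep_s, sep_t), tolerance = 1e-12)
  # mutating one shared weight array changes both domains' outputs
  m$params$fc2_W <- m$params$fc2_W * 2
  zs <- forward_generator(m, xs, rep(1L, 4), mode = "eval")$features
  zt <- forward_generator(m, xt, rep(2L, 4), mode = "eval")$features
  expect_false(isTRUE(all.equal(zs, sep_s)))
  expect_false(isTRUE(all.equal(zt, sep_t)))
})

test_that("backpropagation matches finite differences", {
  model <- build_preset("cross_day", n_classes = 2, input_hw = 12, seed = 5)
  set.seed(2)
  n <- 6
  x <- array(rnorm(n * 5 * 12 * 12), c(n, 5, 12, 12))
  dom <- rep(1:2, each = 3)
  y <- sample(1:2, n, replace = TRUE)
  bn0 <- as.list(model$bn_stats)
  reset_bn <- function() {
    rm(list = ls(model$bn_stats), envir = model$bn_stats)
    for (k in names(bn0)) assign(k, bn0[[k]], model$bn_stats)
  }
  loss_fn <- function() {
    set.seed(99) # freeze dropout
    f <- forward_generator(model, x, dom, mode = "train", keep_cache = TRUE)
    p <- forward_classifier(model, f$features)
    list(loss = classification_loss(p, y), f = f, p = p)
  }
  r <- loss_fn()
  dz <- (r$p - diag(2)[y, ]) / n
  dfeat <- dz %*% t(model$params$cls_W)
  grads <- tdann:::generator_backward(model, r$f$cache, dfeat)
  eps <- 1e-5
  set.seed(31)
  for (k in c("conv2_W", "fc1_W", "bn2_gamma", "bn4_beta")) {
    w <- get(k, model$params)
    for (i in sample(length(w), 3)) {
      w0 <- w[i]
      w[i] <- w0 + eps; assign(k, w, model$params); reset_bn()
      lp <- loss_fn()$loss
      w[i] <- w0 - eps; assign(k, w, model$params); reset_bn()
      lm <- loss_fn()$loss
      w[i] <- w0; assign(k, w, model$params); reset_bn()
      expect_equal(grads[[k]][i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = paste("grad", k, i))
    }
  }
})
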