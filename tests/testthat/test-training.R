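test_that("domain-paired batching covers the source pool exactly once", {
  set.seed(1)
  b <- make_domain_batches(800, 800, 80, 80)
  expect_length(b, 10)
  src_all <- sort(unlist(lapply(b, `[[`, "src")))
  expect_equal(src_all, 1:800) # multiset equality: each source sample once
  for (bb in b) {
    expect_length(bb$src, 80)
    expect_length(bb$tgt, 80)
  }
  # determinism under the seed
  set.seed(99); b1 <- make_domain_batches(300, 200, 50, 50)
  set.seed(99); b2 <- make_domain_batches(300, 200, 50, 50)
  expect_identical(b1, b2)
  # smaller target pool is recycled without replacement within passes:
  # usage counts can differ by at most one
  set.seed(3)
  b3 <- make_domain_batches(400, 90, 80, 80)
  tab <- table(factor(unlist(lapply(b3, `[[`, "tgt")), levels = 1:90))
  expect_lte(max(tab) - min(tab), 1)
  expect_error(make_domain_batches(50, 800, 80, 80), "smaller than one batch")
})

test_that("evaluation metrics are internally consistent", {
  ds <- tiny_benchmark(seed = 21, n_domains = 2)
  tgt <- which(ds$domains == 2)
  src <- which(ds$domains == 1)
  cfg <- tiny_config()
  fit <- train_tdann(list(x = ds$x[src, , , , drop = FALSE],
                          labels = ds$labels[src]),
                     ds$x[tgt, , , , drop = FALSE], cfg)
  m <- evaluate(fit$model, ds$x[tgt, , , , drop = FALSE], ds$labels[tgt],
                domain = 2)
  # confusion-matrix trace / total equals accuracy
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
  expect_equal(rowSums(m$confusion),
               as.numeric(table(factor(ds$labels[tgt], levels = 1:2))),
               ignore_attr = TRUE)
  # class-permuted labels and predictions give identical accuracy
  perm <- c(2L, 1L)
  expect_equal(mean(perm[m$predictions] == perm[ds$labels[tgt]]), m$accuracy)
  # constant classifier scores at the prevalence of the predicted class
  fit$model$params$cls_W[] <- 0
  fit$model$params$cls_b <- c(5, 0) # always predicts class 1
  m2 <- evaluate(fit$model, ds$x[tgt, , , , drop = FALSE], ds$labels[tgt],
                 domain = 2)
  expect_equal(m2$accuracy, mean(ds$labels[tgt] == 1))
})

test_that("training is deterministic and never reads target labels", {
  ds <- tiny_benchmark(seed = 22, n_domains = 2)
  cfg <- tiny_config(max_epochs = 2L)
  r1 <- leave_one_domain_out(ds, cfg)
  r2 <- leave_one_domain_out(ds, cfg)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$folds[[1]]$predictions, r2$folds[[1]]$predictions)
  expect_identical(r1$folds[[1]]$train_metrics$loss_trace,
                   r2$folds[[1]]$train_metrics$loss_trace)
  # label guard: scrambling the held-out domain's labels must not change
  # what the trained model predicts there (only the measured score)
  ds_scr <- ds
  tgt <- which(ds$domains == 2)
  set.seed(1)
  ds_scr$labels[tgt] <- sample(ds$labels[tgt])
  r3 <- leave_one_domain_out(ds_scr, cfg)
  expect_identical(r3$folds[[2]]$predictions, r1$folds[[2]]$predictions)
})

test_that("with adaptation off and no target pool the loop is source-only", {
  ds <- tiny_benchmark(seed = 23, n_domains = 2)
  src <- which(ds$domains == 1); tgt <- which(ds$domains == 2)
  source <- list(x = ds$x[src, , , , drop = FALSE], labels = ds$labels[src])
  xt <- ds$x[tgt, , , , drop = FALSE]
  cfg_a <- tiny_config(lambda_d = 0, lambda_m = 0, adabn = FALSE,
                       transductive = FALSE)
  cfg_b <- tiny_config(lambda_d = 0, lambda_m = 0, adabn = FALSE,
                       transductive = TRUE)
  fit_a <- train_tdann(source, xt, cfg_a)
  fit_b <- train_tdann(source, xt, cfg_b) # target ignored: same result
  expect_identical(fit_a$metrics$loss_trace, fit_b$metrics$loss_trace)
  ma <- evaluate(fit_a$model, xt, ds$labels[tgt], domain = 1, adapt = FALSE)
  mb <- evaluate(fit_b$model, xt, ds$labels[tgt], domain = 1, adapt = FALSE)
  expect_identical(ma$predictions, mb$predictions)
})

test_that("zero domain shift: adaptation matches source-only performance", {
  ds <- tiny_benchmark(seed = 24, n_domains = 2, n_trials = 3, shift = FALSE)
  cfg <- tiny_config(max_epochs = 4L, patience = 4L)
  r_tdann <- leave_one_domain_out(ds, cfg)
  cfg_src <- tiny_config(max_epochs = 4L, patience = 4L, lambda_d = 0,
                         lambda_m = 0, adabn = FALSE, transductive = FALSE)
  r_src <- leave_one_domain_out(ds, cfg_src)
  # identical distributions: the two protocols agree to within noise
  expect_lt(abs(r_tdann$summary["mean"] - r_src$summary["mean"]), 0.05)
  # loocv bookkeeping
  expect_length(r_tdann$folds, 2)
  expect_equal(unname(r_tdann$summary["mean"]), mean(r_tdann$fold_accuracy))
})

test_that("training aborts on invalid configurations", {
  expect_error(adaptation_config(lambda_d = -1), "non-negative")
  expect_error(adaptation_config(val_fraction = 0.6), "val_fraction")
  ds <- tiny_benchmark(seed = 25, n_domains = 2)
  expect_error(leave_one_domain_out(list(x = ds$x, labels = ds$labels,
                                         domains = rep(1L, length(ds$labels))),
                                    tiny_config()),
               "at least 2 domains")
})
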