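# Two-level adversarial training loop: per batch, (a) a discriminator
# step minimizing domain cross-entropy plus the gradient penalty over the
# discriminator parameters, then (b) a generator/classifier step
# minimizing L_C + lambda_d * L_D + lambda_m * L_MMD + lambda_z * ||W||^2
# (with L_D = -H, i.e. domain confusion). Leave-one-domain-out
# cross-validation wraps the loop.

#' Adaptation configuration
#'
#' Bundles every tunable of the training loop. The defaults are the
#' reference cross-day settings: loss weights `lambda_d = 0.1`,
#' `lambda_m = 0.1`, `lambda_z = 0.01`, `lambda_L = 10`, batch 160 split
#' 80 source / 80 target, Adam with learning rate 0.0005, and a 15%
#' validation split. The cross-subject preset uses batch 224 (112/112)
#' and `lambda_L = 0.1`.
#'
#' @param preset network preset name, see [build_preset()].
#' @param lambda_d,lambda_m,lambda_z,lambda_L loss weights (all >= 0).
#' @param batch_source,batch_target per-batch sample counts from the two
#'   pools.
#' @param learning_rate Adam step size.
#' @param max_epochs,patience epoch cap and early-stopping patience (in
#'   epochs without validation-loss improvement).
#' @param val_fraction fraction of each source domain held out for
#'   validation, stratified by class; in (0, 0.5).
#' @param seed integer; the single source of randomness for
#'   initialization, batching, dropout and splits.
#' @param adabn use per-domain normalization statistics; `FALSE` falls
#'   back to standard shared batch normalization.
#' @param transductive use the unlabeled target pool during training;
#'   `FALSE` trains on source only.
#' @param merge_sources present all source domains to the discriminator
#'   as one domain (binary source/target, the default) instead of one
#'   label per source domain.
#' @param mmd_n_kernels,mmd_spacing,mmd_cross_coefficient multi-kernel
#'   MMD settings (see [median_heuristic_bank()] and [mmd2()]).
#' @param gp_eval_points where the Lipschitz penalty is enforced:
#'   `"interpolates"` (random convex combinations of paired
#'   source/target features) or `"at_source_target"`.
#' @return An `adaptation_config` list.
#' @export
adaptation_config <- function(preset = "cross_day",
                              lambda_d = 0.1, lambda_m = 0.1,
                              lambda_z = 0.01, lambda_L = 10,
                              batch_source = 80L, batch_target = 80L,
                              learning_rate = 5e-4,
                              max_epochs = 300L, patience = 20L,
                              val_fraction = 0.15, seed = 1L,
                              adabn = TRUE, transductive = TRUE,
                              merge_sources = TRUE,
                              mmd_n_kernels = 5L, mmd_spacing = 2,
                              mmd_cross_coefficient = 2,
                              gp_eval_points = c("interpolates",
                                                 "at_source_target")) {
  gp_eval_points <- match.arg(gp_eval_points)
  if (any(c(lambda_d, lambda_m, lambda_z, lambda_L) < 0))
    stop("loss weights must be non-negative")
  if (val_fraction <= 0 || val_fraction >= 0.5)
    stop("val_fraction must lie in (0, 0.5)")
  structure(
    list(preset = preset, lambda_d = lambda_d, lambda_m = lambda_m,
         lambda_z = lambda_z, lambda_L = lambda_L,
         batch_source = as.integer(batch_source),
         batch_target = as.integer(batch_target),
         batch_total = as.integer(batch_source + batch_target),
         learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         val_fraction = val_fraction, seed = as.integer(seed),
         adabn = isTRUE(adabn), transductive = isTRUE(transductive),
         merge_sources = isTRUE(merge_sources),
         mmd_n_kernels = as.integer(mmd_n_kernels),
         mmd_spacing = mmd_spacing,
         mmd_cross_coefficient = mmd_cross_coefficient,
         gp_eval_points = gp_eval_points),
    class = "adaptation_config")
}

# stable checksum of a configuration (records provenance in Metrics)
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%.0f", h)
}

# ---- batching --------------------------------------------------------------

#' Domain-paired batch indices for one epoch
#'
#' Every batch draws exactly `batch_source` labelled source samples and
#' `batch_target` unlabeled target samples. Source samples are drawn
#' without replacement (each appears exactly once per epoch); the target
#' pool is cycled through reshuffled permutations as needed; a trailing
#' short batch is dropped.
#'
#' @param n_source,n_target pool sizes.
#' @param batch_source,batch_target per-batch counts.
#' @return List of batches, each `list(src = indices, tgt = indices)`.
#'   Uses the current RNG state (seed upstream for reproducibility).
#' @export
make_domain_batches <- function(n_source, n_target, batch_source = 80L,
                                batch_target = 80L) {
  if (n_source < batch_source || (batch_target > 0 && n_target < batch_target))
    stop("pool smaller than one batch (source ", n_source, "/",
         batch_source, ", target ", n_target, "/", batch_target, ")")
  n_batches <- n_source %/% batch_source
  src_perm <- sample.int(n_source)
  tgt_pool <- integer(0)
  out <- vector("list", n_batches)
  for (i in seq_len(n_batches)) {
    src <- src_perm[((i - 1L) * batch_source + 1L):(i * batch_source)]
    tgt <- integer(0)
    while (length(tgt) < batch_target) {
      if (!length(tgt_pool)) tgt_pool <- sample.int(n_target)
      take <- min(batch_target - length(tgt), length(tgt_pool))
      tgt <- c(tgt, tgt_pool[seq_len(take)])
      tgt_pool <- tgt_pool[-seq_len(take)]
    }
    out[[i]] <- list(src = src, tgt = tgt)
  }
  out
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    m <- state$m[[k]]; v <- state$v[[k]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[k]] <- m; state$v[[k]] <- v
    assign(k, get(k, params) - lr * (m / bc1) / (sqrt(v / bc2) + eps),
           envir = params)
  }
}

# ---- helpers ---------------------------------------------------------------

.onehot <- function(labels, n) {
  y <- matrix(0, length(labels), n)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

# dataset container used by the training loop
#' Convert rendered image stacks into a training dataset
#'
#' Re-orders a `topo_images` stack into the `[n, bands, H, W]` layout the
#' network consumes and recodes labels and domains to dense integer
#' levels.
#'
#' @param topo a `topo_images` object (normally min-max standardized).
#' @return An `image_dataset` list: `x`, `labels` (1..M), `domains`
#'   (1..K), plus the original level codes.
#' @export
as_image_dataset <- function(topo) {
  stopifnot(inherits(topo, "topo_images"))
  x <- aperm(topo$images, c(1, 4, 2, 3))
  lab_lev <- sort(unique(topo$labels))
  dom_lev <- sort(unique(topo$domains))
  structure(
    list(x = x, labels = match(topo$labels, lab_lev),
         domains = match(topo$domains, dom_lev),
         class_levels = lab_lev, domain_levels = dom_lev),
    class = "image_dataset")
}

# stack two [H, W, C, n] arrays along the sample axis
.stack_images <- function(xs, xt) {
  ds <- dim(xs); dt <- dim(xt)
  out <- array(0, c(ds[1], ds[2], ds[3], ds[4] + dt[4]))
  out[, , , seq_len(ds[4])] <- xs
  out[, , , ds[4] + seq_len(dt[4])] <- xt
  out
}

# stratified validation split: per source domain, per class
.val_split <- function(labels, domains, val_fraction) {
  val <- integer(0)
  for (d in unique(domains)) for (cl in unique(labels)) {
    idx <- which(domains == d & labels == cl)
    if (!length(idx)) next
    n_val <- round(length(idx) * val_fraction)
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

.l2_keys <- function(model) {
  keys <- c(grep("^fc[0-9]+_W$", ls(model$params), value = TRUE), "cls_W")
  keys
}

.l2_value <- function(model) {
  sum(vapply(.l2_keys(model), function(k) sum(get(k, model$params)^2),
             numeric(1)))
}

# ---- training --------------------------------------------------------------

#' Train a two-level domain adaptation network
#'
#' Alternates, per batch, a discriminator step (domain cross-entropy plus
#' gradient penalty, discriminator parameters only) and a
#' generator/classifier step (classification loss, domain confusion,
#' multi-kernel MMD and the L2 term). Per-domain normalization statistics
#' are maintained throughout. Training stops early when the validation
#' classification loss has not improved for `patience` epochs; the
#' parameters of the best validation epoch are restored.
#'
#' Target labels are never consumed: the target pool enters unlabeled.
#'
#' @param source an `image_dataset` (or list with `x`, `labels`, and
#'   optionally `domains` used only to stratify the validation split).
#' @param target_x unlabeled target images `[n, bands, H, W]`; may be
#'   `NULL` when the configuration does not use a target pool.
#' @param config an [adaptation_config()].
#' @param verbose print per-epoch loss lines.
#' @return List with the trained `model` and `metrics` (loss traces,
#'   validation trace, best epoch, seed, config hash).
#' @export
train_tdann <- function(source, target_x, config, verbose = FALSE) {
  set.seed(config$seed)
  xs_all <- source$x
  ys_all <- as.integer(source$labels)
  sdom_all <- if (!is.null(source$domains)) as.integer(source$domains) else
    rep(1L, length(ys_all))
  n_classes <- length(unique(ys_all))
  use_target <- config$transductive && !is.null(target_x) &&
    (config$adabn || config$lambda_d > 0 || config$lambda_m > 0)
  model <- build_preset(config$preset, n_classes = n_classes,
                        n_domains = 2L,
                        input_hw = dim(xs_all)[3],
                        n_bands = dim(xs_all)[2], seed = config$seed)
  # merged discriminator/normalization domains: source = 1, target = 2
  val_idx <- .val_split(ys_all, sdom_all, config$val_fraction)
  tr_idx <- setdiff(seq_along(ys_all), val_idx)
  # [H, W, C, n] layout throughout the loop (one transpose per run)
  xs_hw <- aperm(xs_all, c(3, 4, 2, 1))
  xs <- xs_hw[, , , tr_idx, drop = FALSE]
  ys <- ys_all[tr_idx]
  xv <- xs_hw[, , , val_idx, drop = FALSE]
  yv <- ys_all[val_idx]
  rm(xs_hw)
  xt_hw <- if (!is.null(target_x)) aperm(target_x, c(3, 4, 2, 1)) else NULL
  nt <- if (use_target) dim(target_x)[1] else 0L
  opt_gen <- adam_state(); opt_disc <- adam_state()
  p <- model$params
  best <- list(loss = Inf, epoch = 0L, params = NULL, bn = NULL)
  trace <- list()
  ns_b <- config$batch_source
  nt_b <- if (use_target) config$batch_target else 0L
  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_domain_batches(length(ys), max(nt, 1L), ns_b,
                                   if (use_target) nt_b else 0L)
    ep <- c(l_c = 0, l_mmd = 0, h = 0, gp = 0, w2 = 0, l_g = 0)
    for (b in batches) {
      xb <- if (use_target)
        .stack_images(xs[, , , b$src, drop = FALSE],
                      xt_hw[, , , b$tgt, drop = FALSE])
      else xs[, , , b$src, drop = FALSE]
      yb <- ys[b$src]
      nb_s <- length(b$src); nb_t <- if (use_target) length(b$tgt) else 0L
      dom_true <- c(rep(1L, nb_s), rep(2L, nb_t))
      bn_dom <- if (config$adabn) dom_true else rep(1L, nb_s + nb_t)
      fwd <- forward_generator(model, xb, bn_dom, mode = "train",
                               keep_cache = TRUE, layout = "hwcn")
      feat <- fwd$features
      src_rows <- seq_len(nb_s)
      h_val <- 0; gp_val <- 0
      if (config$lambda_d > 0 && nb_t > 0) {
        # (a) discriminator step on current features
        pd <- forward_discriminator(model, feat)
        h_d <- domain_adversarial_loss(pd, dom_true)
        pts <- switch(config$gp_eval_points,
          interpolates = {
            u <- runif(nb_s)
            pair <- feat[nb_s + (seq_len(nb_s) - 1L) %% nb_t + 1L, , drop = FALSE]
            u * feat[src_rows, , drop = FALSE] + (1 - u) * pair
          },
          at_source_target = feat)
        gp_val <- gradient_penalty(discriminator_head(model), pts)
        dz <- (pd - .onehot(dom_true, 2L)) / nrow(pd)
        w1 <- p$disc_W[, 1]
        nw1 <- sqrt(sum(w1^2))
        dgp_w1 <- if (nw1 > 0) 2 * (nw1 - 1) * w1 / nw1 else rep(0, length(w1))
        dW <- crossprod(feat, dz)
        dW[, 1] <- dW[, 1] + config$lambda_L * dgp_w1
        adam_update(p, list(disc_W = dW, disc_b = colSums(dz)),
                    opt_disc, config$learning_rate)
      }
      # (b) generator/classifier step (updated discriminator)
      dfeat <- matrix(0, nrow(feat), ncol(feat))
      pc <- forward_classifier(model, feat[src_rows, , drop = FALSE])
      l_c <- classification_loss(pc, yb)
      dzc <- (pc - .onehot(yb, n_classes)) / nb_s
      dfeat[src_rows, ] <- dzc %*% t(p$cls_W)
      head_grads <- list(cls_W = crossprod(feat[src_rows, , drop = FALSE], dzc) +
                           2 * config$lambda_z * p$cls_W,
                         cls_b = colSums(dzc))
      l_mmd <- 0
      if (config$lambda_m > 0 && nb_t > 0) {
        fs <- feat[src_rows, , drop = FALSE]
        ft <- feat[nb_s + seq_len(nb_t), , drop = FALSE]
        bank <- median_heuristic_bank(fs, ft, config$mmd_n_kernels,
                                      config$mmd_spacing)
        l_mmd <- mmd2(fs, ft, bank, config$mmd_cross_coefficient)
        mg <- .mmd2_grad(fs, ft, bank, config$mmd_cross_coefficient)
        dfeat[src_rows, ] <- dfeat[src_rows, ] + config$lambda_m * mg$source
        dfeat[nb_s + seq_len(nb_t), ] <-
          dfeat[nb_s + seq_len(nb_t), ] + config$lambda_m * mg$target
      }
      if (config$lambda_d > 0 && nb_t > 0) {
        pd2 <- forward_discriminator(model, feat)
        h_val <- domain_adversarial_loss(pd2, dom_true)
        dzd <- (pd2 - .onehot(dom_true, 2L)) / nrow(pd2)
        dfeat <- dfeat - config$lambda_d * (dzd %*% t(p$disc_W))
      }
      grads <- generator_backward(model, fwd$cache, dfeat)
      for (k in grep("^fc[0-9]+_W$", names(grads), value = TRUE))
        grads[[k]] <- grads[[k]] + 2 * config$lambda_z * get(k, p)
      grads <- c(grads, head_grads)
      adam_update(p, grads, opt_gen, config$learning_rate)
      w2 <- .l2_value(model)
      l_g <- generator_objective(l_c, h_val, l_mmd, w2, config$lambda_d,
                                 config$lambda_m, config$lambda_z)
      if (!is.finite(l_g)) {
        comps <- c(L_C = l_c, H = h_val, L_MMD = l_mmd, W2 = w2)
        stop("non-finite training loss; components: ",
             paste(names(comps), signif(comps, 4), sep = "=",
                   collapse = ", "))
      }
      ep <- ep + c(l_c, l_mmd, h_val, gp_val, w2, l_g)
    }
    ep <- ep / length(batches)
    # validation under source-domain statistics
    pv <- forward_classifier(model,
      forward_generator(model, xv, rep(1L, dim(xv)[4]),
                        mode = "eval", layout = "hwcn")$features)
    val_loss <- classification_loss(pv, yv)
    val_acc <- mean(max.col(pv) == yv)
    trace[[epoch]] <- c(epoch = epoch, ep, val_loss = val_loss,
                        val_acc = val_acc)
    if (verbose)
      message(sprintf(
        "epoch %3d  L_C %.4f  L_MMD %.4f  H %.4f  GP %.4f  val %.4f (acc %.3f)",
        epoch, ep["l_c"], ep["l_mmd"], ep["h"], ep["gp"], val_loss, val_acc))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, epoch = epoch,
                   params = as.list(p),
                   bn = as.list(model$bn_stats))
    } else if (epoch - best$epoch >= config$patience) break
  }
  if (!is.null(best$params)) {
    for (k in names(best$params)) assign(k, best$params[[k]], envir = p)
    rm(list = ls(model$bn_stats), envir = model$bn_stats)
    for (k in names(best$bn)) assign(k, best$bn[[k]], envir = model$bn_stats)
  }
  metrics <- structure(
    list(loss_trace = do.call(rbind, trace), best_epoch = best$epoch,
         best_val_loss = best$loss, seed = config$seed,
         config_hash = config_hash(config), n_epochs = length(trace)),
    class = "tdann_metrics")
  list(model = model, metrics = metrics)
}

#' Evaluate a trained model on a labelled test domain
#'
#' Runs the AdaBN adapt pass on the (unlabeled) test images to install
#' the domain's normalization statistics, then scores predictions in
#' eval mode. No parameters are updated.
#'
#' @param model a trained model from [train_tdann()].
#' @param x test images `[n, bands, H, W]`.
#' @param labels integer test labels (used for scoring only).
#' @param domain normalization domain of the test set (2 = target under
#'   the merged source/target convention).
#' @param adapt run the adapt pass on `x` first (default); if `FALSE`
#'   the domain's statistics must already exist.
#' @return A `tdann_metrics` list with `accuracy`, `per_class_accuracy`,
#'   `confusion` and `predictions`.
#' @export
evaluate <- function(model, x, labels, domain = 2L, adapt = TRUE) {
  labels <- as.integer(labels)
  if (adapt) adabn_adapt(model, x, domain)
  feats <- forward_generator(model, x, rep(as.integer(domain), dim(x)[1]),
                             mode = "eval")$features
  probs <- forward_classifier(model, feats)
  pred <- max.col(probs)
  n_classes <- model$n_classes
  confusion <- table(factor(labels, levels = seq_len(n_classes)),
                     factor(pred, levels = seq_len(n_classes)))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(
    list(accuracy = mean(pred == labels),
         per_class_accuracy = as.numeric(per_class),
         confusion = unclass(confusion), predictions = pred,
         loss = classification_loss(probs, labels)),
    class = "tdann_metrics")
}

#' Leave-one-domain-out cross-validation
#'
#' Each domain (day or subject) serves once as the held-out target/test
#' set while the remaining domains form the labelled source pool; the
#' target's images participate in training unlabeled (transductive
#' protocol) unless the configuration disables it. Within each fold a
#' stratified validation split (default 15%) of every source domain
#' drives early stopping.
#'
#' @param dataset an `image_dataset` (see [as_image_dataset()]) with at
#'   least 2 domains.
#' @param config an [adaptation_config()]; fold f trains with seed
#'   `config$seed + 7919 * f`.
#' @param verbose print per-fold accuracy lines.
#' @return List with per-fold metrics (`folds`), `fold_accuracy`, and
#'   `summary` (mean and standard deviation of the fold accuracies).
#' @export
leave_one_domain_out <- function(dataset, config, verbose = FALSE) {
  domains <- sort(unique(dataset$domains))
  if (length(domains) < 2) stop("need at least 2 domains")
  folds <- list()
  accs <- numeric(0)
  for (f in seq_along(domains)) {
    dk <- domains[f]
    tgt <- which(dataset$domains == dk)
    src <- which(dataset$domains != dk)
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919 * f) %% 2147483647)
    source <- list(x = dataset$x[src, , , , drop = FALSE],
                   labels = dataset$labels[src],
                   domains = dataset$domains[src])
    fit <- train_tdann(source, dataset$x[tgt, , , , drop = FALSE], cfg)
    use_adapt <- cfg$adabn
    m <- evaluate(fit$model, dataset$x[tgt, , , , drop = FALSE],
                  dataset$labels[tgt],
                  domain = if (cfg$adabn) 2L else 1L, adapt = use_adapt)
    m$train_metrics <- fit$metrics
    m$target_domain <- dk
    folds[[f]] <- m
    accs <- c(accs, m$accuracy)
    if (verbose)
      message(sprintf("fold %d (domain %s): accuracy %.3f", f, dk,
                      m$accuracy))
  }
  list(folds = folds, fold_accuracy = accs,
       summary = c(mean = mean(accs), sd = stats::sd(accs)))
}
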