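# Feature generator G_f (CNN), classifier G_c and domain discriminator
# G_d, with adaptive batch normalization (per-domain statistics, shared
# affine parameters) and dropout. Forward and backward passes are
# implemented directly (im2col convolutions through the compiled kernels,
# everything else in matrix form) so every gradient used in training --
# including input gradients for the penalty -- is analytic.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ---- layer arithmetic ------------------------------------------------------

conv_out <- function(hw) hw - 2L              # valid 3x3 convolution
pool_out <- function(hw) as.integer(ceiling(hw / 2)) # 2x2 ceil-mode pooling

# generator layer sequences; dense sizes from the reference TDANN architectures, the
# flatten width is always computed from the actual spatial dimensions
preset_layers <- function(name) {
  switch(name,
    cross_day = list(
      conv = list(c(5L, 6L), c(6L, 64L)),
      conv_pool_after = c(1L, 2L),            # pool after these conv indices
      dense = c(512L, 256L)),
    cross_subject = list(
      conv = list(c(5L, 32L), c(32L, 32L), c(32L, 64L), c(64L, 64L),
                  c(64L, 128L), c(128L, 128L)),
      conv_pool_after = c(2L, 6L),
      dense = c(1024L, 512L, 256L)),
    stop("unknown preset '", name, "' (use cross_day or cross_subject)"))
}

#' Build a network preset
#'
#' Constructs the feature generator, classifier and domain discriminator
#' for one of the two reference TDANN architectures. `cross_day` is the compact
#' model (conv 5-6-64 with two pooling stages, dense 512-256);
#' `cross_subject` is the deeper one (conv 5-32-32-64-64-128-128, dense
#' 1024-512-256). Convolutions are unpadded ("valid") and pooling is 2x2
#' in ceil mode, the only convention under which the compact model's
#' reference flatten size (7 x 7 x 64 for 32 x 32 input) is reproduced; the
#' flatten width is nevertheless always computed from the actual spatial
#' dimensions. The deeper preset's reference flatten size is not consistent
#' with any standard convention for a 32 x 32 input, so the computed size
#' is used there too. Adaptive batch normalization follows every
#' convolution and dense layer; dense layers carry dropout 0.5; hidden
#' activations are ReLU; both heads are single dense layers with softmax
#' outputs on the 256-d feature.
#'
#' @param name `"cross_day"` or `"cross_subject"`.
#' @param n_classes number of emotion classes M (>= 2).
#' @param n_domains number of domain labels N seen by the discriminator
#'   (>= 2; source/target merging gives 2).
#' @param input_hw input image side length in pixels (default 32).
#' @param n_bands number of image channels (default 5).
#' @param seed integer seed for the fan-in-scaled random initialization.
#' @return A `tdann_model` environment holding the layer specification,
#'   parameters and per-domain normalization state.
#' @export
build_preset <- function(name = c("cross_day", "cross_subject"),
                         n_classes, n_domains = 2L, input_hw = 32L,
                         n_bands = 5L, seed = 1L) {
  name <- match.arg(name)
  stopifnot(n_classes >= 2, n_domains >= 2)
  arch <- preset_layers(name)
  if (arch$conv[[1]][1] != n_bands)
    arch$conv[[1]][1] <- as.integer(n_bands)
  model <- new.env(parent = emptyenv())
  model$preset <- name
  model$n_classes <- as.integer(n_classes)
  model$n_domains <- as.integer(n_domains)
  model$input_shape <- c(input_hw, input_hw, n_bands)
  params <- new.env(parent = emptyenv())
  layers <- list()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  hw <- as.integer(input_hw)
  bi <- 0L
  add_bn <- function(width) {
    bi <<- bi + 1L
    nm <- paste0("bn", bi)
    assign(paste0(nm, "_gamma"), rep(1, width), envir = params)
    assign(paste0(nm, "_beta"), rep(0, width), envir = params)
    nm
  }
  for (i in seq_along(arch$conv)) {
    io <- arch$conv[[i]]
    fan_in <- 9L * io[1]
    assign(paste0("conv", i, "_W"),
           array(rnorm(9L * io[1] * io[2], sd = sqrt(2 / fan_in)),
                 c(3L, 3L, io[1], io[2])), envir = params)
    assign(paste0("conv", i, "_b"), rep(0, io[2]), envir = params)
    layers[[length(layers) + 1L]] <- list(kind = "conv", name = paste0("conv", i),
                                          cin = io[1], cout = io[2], hw_in = hw)
    hw <- conv_out(hw)
    layers[[length(layers) + 1L]] <- list(kind = "adabn", name = add_bn(io[2]),
                                          width = io[2], conv = TRUE)
    layers[[length(layers) + 1L]] <- list(kind = "relu")
    if (i %in% arch$conv_pool_after) {
      layers[[length(layers) + 1L]] <- list(kind = "pool", hw_in = hw,
                                            channels = io[2])
      hw <- pool_out(hw)
    }
  }
  flat <- hw * hw * arch$conv[[length(arch$conv)]][2]
  layers[[length(layers) + 1L]] <- list(kind = "flatten", hw = hw,
                                        channels = arch$conv[[length(arch$conv)]][2])
  din <- flat
  for (i in seq_along(arch$dense)) {
    dout <- arch$dense[i]
    assign(paste0("fc", i, "_W"),
           matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
           envir = params)
    assign(paste0("fc", i, "_b"), rep(0, dout), envir = params)
    layers[[length(layers) + 1L]] <- list(kind = "dense", name = paste0("fc", i),
                                          din = din, dout = dout)
    layers[[length(layers) + 1L]] <- list(kind = "adabn", name = add_bn(dout),
                                          width = dout, conv = FALSE)
    layers[[length(layers) + 1L]] <- list(kind = "relu")
    layers[[length(layers) + 1L]] <- list(kind = "dropout", rate = 0.5)
    din <- dout
  }
  feature_dim <- din
  assign("cls_W", matrix(rnorm(feature_dim * n_classes,
                               sd = sqrt(1 / feature_dim)),
                         feature_dim, n_classes), envir = params)
  assign("cls_b", rep(0, n_classes), envir = params)
  assign("disc_W", matrix(rnorm(feature_dim * n_domains,
                                sd = sqrt(1 / feature_dim)),
                          feature_dim, n_domains), envir = params)
  assign("disc_b", rep(0, n_domains), envir = params)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  model$layers <- layers
  model$feature_dim <- feature_dim
  model$flatten_shape <- c(hw, hw, arch$conv[[length(arch$conv)]][2])
  model$params <- params
  model$bn_stats <- new.env(parent = emptyenv()) # "<bn>_<domain>" -> list(mean, var)
  model$seed <- as.integer(seed)
  class(model) <- "tdann_model"
  model
}

#' @export
print.tdann_model <- function(x, ...) {
  cat(sprintf("<tdann_model> preset %s: %d-d features, %d classes, %d domains\n",
              x$preset, x$feature_dim, x$n_classes, x$n_domains))
  cat(sprintf("  flatten %d x %d x %d = %d\n", x$flatten_shape[1],
              x$flatten_shape[2], x$flatten_shape[3],
              prod(x$flatten_shape)))
  invisible(x)
}

# ---- primitive forward/backward -------------------------------------------

.conv_forward <- function(x, W, b, chunk = 256L) {
  d <- dim(x)
  nb <- d[4]
  Wm <- matrix(W, ncol = dim(W)[4])
  oh <- d[1] - 2L; ow <- d[2] - 2L
  cout <- dim(W)[4]
  if (nb <= chunk) {
    r <- cpp_conv_forward(x, d, Wm, b)
    return(list(out = r$out, cols = list(r$col), in_dim = d, chunk = chunk))
  }
  out <- array(0, c(oh, ow, cout, nb))
  cols <- vector("list", ceiling(nb / chunk))
  ci <- 0L
  for (from in seq(1L, nb, by = chunk)) {
    to <- min(from + chunk - 1L, nb)
    r <- cpp_conv_forward(x[, , , from:to, drop = FALSE],
                          c(d[1], d[2], d[3], to - from + 1L), Wm, b)
    out[, , , from:to] <- r$out
    ci <- ci + 1L
    cols[[ci]] <- r$col
  }
  list(out = out, cols = cols, in_dim = d, chunk = chunk)
}

.conv_backward <- function(cache, W, dout, need_dx = TRUE) {
  d <- cache$in_dim
  nb <- d[4]
  Wm <- matrix(W, ncol = dim(W)[4])
  cout <- dim(W)[4]
  if (nb <= cache$chunk) {
    r <- cpp_conv_backward(cache$cols[[1]], d, Wm, dout, need_dx)
    return(list(dW = array(r$dW, dim(W)), db = r$db, dx = r$dx))
  }
  dW <- matrix(0, nrow(Wm), cout)
  db <- numeric(cout)
  dx <- if (need_dx) array(0, d) else NULL
  ci <- 0L
  for (from in seq(1L, nb, by = cache$chunk)) {
    to <- min(from + cache$chunk - 1L, nb)
    ci <- ci + 1L
    r <- cpp_conv_backward(cache$cols[[ci]],
                           c(d[1], d[2], d[3], to - from + 1L), Wm,
                           dout[, , , from:to, drop = FALSE], need_dx)
    dW <- dW + r$dW
    db <- db + r$db
    if (need_dx) dx[, , , from:to] <- r$dx
  }
  list(dW = array(dW, dim(W)), db = db, dx = dx)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Core per-domain batch normalization on a (groups x channels) moment
# representation: x_mat is (m x (channels*batch)) where each column is one
# (channel, sample) cell averaged over m spatial positions (m = 1 for
# dense layers).
.bn_stats_from_moments <- function(cm, sq, batch_idx) {
  mu <- rowMeans(cm[, batch_idx, drop = FALSE])
  ex2 <- rowMeans(sq[, batch_idx, drop = FALSE])
  list(mean = mu, var = pmax(ex2 - mu^2, 0))
}

# ---- generator forward / backward -----------------------------------------

#' Run the feature generator
#'
#' @param model a [build_preset()] model.
#' @param images numeric array `[batch, bands, H, W]`.
#' @param domains integer domain label per sample (drives the adaptive
#'   normalization statistics).
#' @param mode `"train"` (per-domain batch statistics, running statistics
#'   updated, dropout active), `"eval"` (stored statistics of each
#'   sample's domain, dropout off) or `"adapt"` (single-domain pool:
#'   statistics recomputed over the pool and stored, dropout off).
#' @param keep_cache keep layer caches for a subsequent backward pass.
#' @param layout `"nchw"` for the standard `[batch, bands, H, W]` input
#'   (the default) or `"hwcn"` for pre-transposed `[H, W, bands, batch]`
#'   arrays (used internally by the training loop to avoid per-batch
#'   transposes).
#' @return List with `features` `[batch, feature_dim]` and (if requested)
#'   `cache`.
#' @export
forward_generator <- function(model, images, domains,
                              mode = c("train", "eval", "adapt"),
                              keep_cache = FALSE,
                              layout = c("nchw", "hwcn")) {
  mode <- match.arg(mode)
  layout <- match.arg(layout)
  d <- dim(images)
  ok <- if (layout == "nchw")
    length(d) == 4L && d[3] == model$input_shape[1] &&
      d[4] == model$input_shape[2] && d[2] == model$input_shape[3]
  else
    length(d) == 4L && d[1] == model$input_shape[1] &&
      d[2] == model$input_shape[2] && d[3] == model$input_shape[3]
  if (!ok)
    stop("input shape [", paste(d, collapse = ", "),
         "] does not match preset expectation [batch, ",
         model$input_shape[3], ", ", model$input_shape[1], ", ",
         model$input_shape[2], "]")
  nb <- if (layout == "nchw") d[1] else d[4]
  domains <- as.integer(domains)
  if (length(domains) != nb) stop("one domain label per sample required")
  if (mode == "adapt" && length(unique(domains)) != 1L)
    stop("adapt mode expects a single-domain pool")
  if (mode == "train") {
    cnt <- table(domains)
    if (any(cnt < 2))
      stop("train mode needs >= 2 samples per domain in the batch (got ",
           paste(names(cnt)[cnt < 2], collapse = ", "), ")")
  }
  p <- model$params
  x <- if (layout == "nchw") aperm(images, c(3, 4, 2, 1)) else images
  cache <- if (keep_cache) list(domains = domains, mode = mode) else NULL
  caches <- list()
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    if (L$kind == "conv") {
      cf <- .conv_forward(x, get(paste0(L$name, "_W"), p),
                          get(paste0(L$name, "_b"), p))
      if (keep_cache) caches[[li]] <- cf[c("cols", "in_dim", "chunk")]
      x <- cf$out
    } else if (L$kind == "pool") {
      pf <- cpp_maxpool2(as.numeric(x), dim(x))
      if (keep_cache) caches[[li]] <- list(argmax = pf$argmax, in_dim = dim(x))
      x <- pf$out
    } else if (L$kind == "flatten") {
      if (keep_cache) caches[[li]] <- list(in_dim = dim(x))
      x <- t(matrix(x, ncol = dim(x)[4]))
    } else if (L$kind == "dense") {
      W <- get(paste0(L$name, "_W"), p)
      if (keep_cache) caches[[li]] <- list(x = x)
      x <- sweep(x %*% W, 2, get(paste0(L$name, "_b"), p), "+")
    } else if (L$kind == "adabn") {
      r <- .adabn_layer(model, L, x, domains, mode, keep_cache)
      if (keep_cache) caches[[li]] <- r$cache
      x <- r$out
    } else if (L$kind == "relu") {
      if (keep_cache) caches[[li]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (L$kind == "dropout") {
      if (mode == "train") {
        mask <- matrix(runif(length(x)) >= L$rate, nrow(x), ncol(x)) /
          (1 - L$rate)
        if (keep_cache) caches[[li]] <- list(mask = mask)
        x <- x * mask
      } else if (keep_cache) caches[[li]] <- list(mask = NULL)
    }
  }
  if (keep_cache) {
    cache$layers <- caches
    list(features = x, cache = cache)
  } else {
    list(features = x)
  }
}

# AdaBN layer forward on either conv arrays [h,w,c,B] or dense matrices
# [B, c]; per-domain statistics, shared affine parameters. The data is
# handled as an (m x cw*nb) column block (m spatial positions; columns
# ordered channel-fastest, then sample) and the normalization itself runs
# in the compiled kernel.
.adabn_layer <- function(model, L, x, domains, mode, keep_cache) {
  p <- model$params
  gamma <- get(paste0(L$name, "_gamma"), p)
  beta <- get(paste0(L$name, "_beta"), p)
  conv <- isTRUE(L$conv)
  if (conv) {
    d <- dim(x); m <- d[1] * d[2]; cw <- d[3]; nb <- d[4]
    xv <- x
  } else {
    nb <- nrow(x); cw <- length(gamma); m <- 1L
    xv <- t(x)
  }
  K <- cw * nb
  cm <- matrix(.colMeans(xv, m, K), cw, nb)
  sq <- matrix(.colMeans(xv * xv, m, K), cw, nb)
  mu_full <- numeric(K); var_full <- numeric(K)
  for (g in unique(domains)) {
    idx <- which(domains == g)
    key <- paste0(L$name, "_", g)
    if (mode == "eval") {
      st <- model$bn_stats[[key]]
      if (is.null(st))
        stop("no stored normalization statistics for domain ", g,
             " (run an adapt pass first)")
    } else {
      st <- .bn_stats_from_moments(cm, sq, idx)
      if (mode == "train") {
        old <- model$bn_stats[[key]]
        model$bn_stats[[key]] <- if (is.null(old)) st else
          list(mean = (1 - BN_MOMENTUM) * old$mean + BN_MOMENTUM * st$mean,
               var = (1 - BN_MOMENTUM) * old$var + BN_MOMENTUM * st$var)
      } else { # adapt: store the pool statistics verbatim
        model$bn_stats[[key]] <- st
      }
    }
    cols <- as.vector(outer(seq_len(cw), (idx - 1L) * cw, "+"))
    mu_full[cols] <- st$mean
    var_full[cols] <- st$var
  }
  inv_full <- 1 / sqrt(var_full + BN_EPS)
  r <- cpp_bn_forward(xv, m, mu_full, inv_full, rep(gamma, nb),
                      rep(beta, nb))
  cache <- NULL
  if (keep_cache)
    cache <- list(xhat = r$xhat, inv_full = inv_full, conv = conv, m = m,
                  cw = cw, nb = nb, dims = if (conv) dim(x) else NULL)
  out <- if (conv) array(r$y, dim(x)) else t(matrix(r$y, cw, nb))
  list(out = out, cache = cache)
}

# backward through an AdaBN layer (train-mode batch statistics)
.adabn_backward <- function(model, L, cache, dy_raw, domains) {
  p <- model$params
  gamma <- get(paste0(L$name, "_gamma"), p)
  m <- cache$m; cw <- cache$cw; nb <- cache$nb
  K <- cw * nb
  dy <- if (cache$conv) dy_raw else t(dy_raw)
  s1 <- .colMeans(dy, m, K) * m             # per-(channel, sample) sums
  s2 <- .colMeans(dy * cache$xhat, m, K) * m
  s1m <- matrix(s1, cw, nb); s2m <- matrix(s2, cw, nb)
  dbeta <- rowSums(s1m)
  dgamma <- rowSums(s2m)
  md <- numeric(K); mdx <- numeric(K); ge <- numeric(K)
  for (g in unique(domains)) {
    idx <- which(domains == g)
    ng <- m * length(idx)
    cols <- as.vector(outer(seq_len(cw), (idx - 1L) * cw, "+"))
    md[cols] <- rowSums(s1m[, idx, drop = FALSE]) / ng
    mdx[cols] <- rowSums(s2m[, idx, drop = FALSE]) / ng
    ge[cols] <- gamma * cache$inv_full[cols[seq_len(cw)]]
  }
  dx <- cpp_bn_backward(dy, cache$xhat, m, md, mdx, ge)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Backward pass through the generator given d(loss)/d(features).
# Returns a named list of parameter gradients.
generator_backward <- function(model, cache, dfeat) {
  p <- model$params
  domains <- cache$domains
  grads <- list()
  dx <- dfeat
  for (li in rev(seq_along(model$layers))) {
    L <- model$layers[[li]]
    cc <- cache$layers[[li]]
    if (L$kind == "dropout") {
      if (!is.null(cc$mask)) dx <- dx * cc$mask
    } else if (L$kind == "relu") {
      dx <- dx * cc$mask
    } else if (L$kind == "adabn") {
      r <- .adabn_backward(model, L, cc, dx, domains)
      grads[[paste0(L$name, "_gamma")]] <- r$dgamma
      grads[[paste0(L$name, "_beta")]] <- r$dbeta
      dx <- if (cc$conv) array(r$dx, cc$dims) else t(matrix(r$dx, cc$cw, cc$nb))
    } else if (L$kind == "dense") {
      W <- get(paste0(L$name, "_W"), p)
      grads[[paste0(L$name, "_W")]] <- crossprod(cc$x, dx)
      grads[[paste0(L$name, "_b")]] <- colSums(dx)
      dx <- dx %*% t(W)
    } else if (L$kind == "flatten") {
      dx <- array(t(dx), cc$in_dim)
    } else if (L$kind == "pool") {
      dx <- cpp_maxpool2_backward(as.numeric(dx), cc$argmax, cc$in_dim)
    } else if (L$kind == "conv") {
      W <- get(paste0(L$name, "_W"), p)
      r <- .conv_backward(cc, W, dx, need_dx = li > 1L)
      grads[[paste0(L$name, "_W")]] <- r$dW
      grads[[paste0(L$name, "_b")]] <- r$db
      dx <- r$dx
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- heads -----------------------------------------------------------------

.head_forward <- function(W, b, features) {
  .softmax(sweep(features %*% W, 2, b, "+"))
}

#' Classifier forward pass
#'
#' @param model a [build_preset()] model.
#' @param features `[batch, feature_dim]` generator output.
#' @return `[batch, M]` matrix of class probabilities (rows sum to 1).
#' @export
forward_classifier <- function(model, features) {
  .head_forward(model$params$cls_W, model$params$cls_b, features)
}

#' Domain discriminator forward pass
#'
#' @inheritParams forward_classifier
#' @return `[batch, N]` matrix of domain probabilities.
#' @export
forward_discriminator <- function(model, features) {
  .head_forward(model$params$disc_W, model$params$disc_b, features)
}

# discriminator head as a standalone object (for the gradient penalty)
discriminator_head <- function(model) {
  structure(list(W = model$params$disc_W, b = model$params$disc_b),
            class = "dense_head")
}

#' Standalone adaptive batch normalization
#'
#' Normalizes each domain's sub-batch by its own statistics and applies
#' the shared affine transform. This is the functional form of the layer
#' used inside the generator, operating on `[batch, features]` matrices;
#' it carries its running state in the returned object.
#'
#' @param x `[batch, features]` activations.
#' @param domain_ids integer domain per row.
#' @param gamma,beta shared affine parameters (scalars are recycled).
#' @param state list of per-domain statistics from a previous call, or
#'   `NULL`.
#' @param mode `"train"`, `"adapt"` or `"eval"` (see
#'   [forward_generator()]).
#' @param momentum running-statistics update rate in train mode.
#' @return List with `out` (normalized activations) and `state`.
#' @export
adabn_forward <- function(x, domain_ids, gamma = 1, beta = 0, state = NULL,
                          mode = c("train", "adapt", "eval"),
                          momentum = BN_MOMENTUM) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  nf <- ncol(x)
  if (length(gamma) == 1L) gamma <- rep(gamma, nf)
  if (length(beta) == 1L) beta <- rep(beta, nf)
  domain_ids <- as.integer(domain_ids)
  if (length(domain_ids) != nrow(x)) stop("one domain id per row required")
  if (is.null(state)) state <- list()
  out <- x
  for (g in unique(domain_ids)) {
    idx <- which(domain_ids == g)
    key <- as.character(g)
    if (mode == "eval") {
      st <- state[[key]]
      if (is.null(st)) stop("unseen domain ", g, " in eval mode")
    } else {
      if (mode == "train" && length(idx) < 2)
        stop("domain ", g, " has fewer than 2 samples in train mode")
      mu <- colMeans(x[idx, , drop = FALSE])
      v <- colMeans(x[idx, , drop = FALSE]^2) - mu^2
      st <- list(mean = mu, var = pmax(v, 0))
      old <- state[[key]]
      state[[key]] <- if (mode == "adapt" || is.null(old)) st else
        list(mean = (1 - momentum) * old$mean + momentum * st$mean,
             var = (1 - momentum) * old$var + momentum * st$var)
      # train mode normalizes by the batch statistics themselves
    }
    xh <- sweep(sweep(x[idx, , drop = FALSE], 2, st$mean), 2,
                sqrt(st$var + BN_EPS), "/")
    out[idx, ] <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  }
  list(out = out, state = state)
}

#' Recompute a domain's normalization statistics
#'
#' The AdaBN "adapt" pass: propagates an unlabeled pool of one domain
#' through the generator, recomputing and storing that domain's
#' statistics at every normalization layer (layer by layer, so deeper
#' statistics are computed under the already-updated shallower ones).
#'
#' @param model a [build_preset()] model.
#' @param images `[batch, bands, H, W]` pool of the domain's samples.
#' @param domain the domain identifier.
#' @return The model, invisibly (state updated in place).
#' @export
adabn_adapt <- function(model, images, domain) {
  forward_generator(model, images, rep(as.integer(domain), dim(images)[1]),
                    mode = "adapt")
  invisible(model)
}
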