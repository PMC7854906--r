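# The two-level objective: source classification cross-entropy,
# multi-kernel MMD between source and target features, domain-adversarial
# cross-entropy, a gradient penalty on the discriminator, and the L2 term
# on dense weights. All losses are plain functions of probabilities /
# features so they can be unit-tested against explicit oracles.

#' Multi-RBF kernel bank
#'
#' A linear combination of radial basis function kernels
#' `sum_n eta_n * exp(-||x - y||^2 / (2 * sigma_n))`, where `sigma_n` is
#' on the squared-distance scale and the weights `eta_n` are normalized
#' to sum to one.
#'
#' @param sigmas positive bandwidths (squared-distance scale).
#' @param weights non-negative kernel weights; normalized internally.
#' @return A `kernel_bank` object.
#' @export
kernel_bank <- function(sigmas, weights = rep(1, length(sigmas))) {
  sigmas <- as.numeric(sigmas); weights <- as.numeric(weights)
  if (length(sigmas) != length(weights))
    stop("sigmas and weights must have equal length")
  if (any(sigmas <= 0)) stop("all bandwidths must be positive")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  structure(list(sigmas = sigmas, weights = weights / sum(weights)),
            class = "kernel_bank")
}

#' Evaluate the multi-kernel on a pair of feature vectors
#'
#' @param x,y feature vectors of equal dimension.
#' @param bank a [kernel_bank()].
#' @return Scalar kernel value; equals 1 at `x == y` (weights normalized).
#' @export
mk_kernel <- function(x, y, bank) {
  if (length(x) != length(y)) stop("feature dimensions differ")
  d2 <- sum((x - y)^2)
  sum(bank$weights * exp(-d2 / (2 * bank$sigmas)))
}

# pairwise multi-kernel Gram matrix between the rows of X and Y
.mk_gram <- function(X, Y, bank) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  K <- matrix(0, nrow(X), nrow(Y))
  for (k in seq_along(bank$sigmas))
    K <- K + bank$weights[k] * exp(-d2 / (2 * bank$sigmas[k]))
  K
}

#' Squared maximum mean discrepancy between two feature sets
#'
#' Biased V-statistic estimate
#' `mean(K_SS) - c * mean(K_ST) + mean(K_TT)`. With the default cross
#' coefficient `c = 2` the estimate is non-negative and vanishes when the
#' two samples coincide; `c = 1` is also accepted (it drops the factor 2
#' on the cross term, at the price of possibly negative values).
#'
#' @param features_s,features_t numeric matrices `[n, d]` of source and
#'   target features; a plain vector is treated as one d-dimensional
#'   sample.
#' @param bank a [kernel_bank()].
#' @param cross_coefficient 2 (default) or 1.
#' @return Scalar squared MMD.
#' @export
mmd2 <- function(features_s, features_t, bank, cross_coefficient = 2) {
  if (is.null(dim(features_s))) features_s <- matrix(features_s, nrow = 1)
  if (is.null(dim(features_t))) features_t <- matrix(features_t, nrow = 1)
  if (nrow(features_s) < 1 || nrow(features_t) < 1)
    stop("both feature sets must be non-empty")
  if (!cross_coefficient %in% c(1, 2))
    stop("cross_coefficient must be 1 or 2")
  mean(.mk_gram(features_s, features_s, bank)) -
    cross_coefficient * mean(.mk_gram(features_s, features_t, bank)) +
    mean(.mk_gram(features_t, features_t, bank))
}

# MMD gradient with respect to the source and target feature rows
# (cross_coefficient = 2 path used in training).
.mmd2_grad <- function(fs, ft, bank, cross_coefficient = 2) {
  ns <- nrow(fs); nt <- nrow(ft)
  gs <- matrix(0, ns, ncol(fs)); gt <- matrix(0, nt, ncol(ft))
  d2ss <- outer(rowSums(fs^2), rowSums(fs^2), "+") - 2 * tcrossprod(fs)
  d2tt <- outer(rowSums(ft^2), rowSums(ft^2), "+") - 2 * tcrossprod(ft)
  d2st <- outer(rowSums(fs^2), rowSums(ft^2), "+") - 2 * tcrossprod(fs, ft)
  for (k in seq_along(bank$sigmas)) {
    s <- bank$sigmas[k]; w <- bank$weights[k]
    Kss <- exp(-pmax(d2ss, 0) / (2 * s))
    Ktt <- exp(-pmax(d2tt, 0) / (2 * s))
    Kst <- exp(-pmax(d2st, 0) / (2 * s))
    # d/dx_i of mean(Kss): (2 / ns^2) * sum_j Kss[i,j] * (x_i - x_j) * (-1/s)
    gs <- gs - w * (2 / (ns^2 * s)) * (rowSums(Kss) * fs - Kss %*% fs)
    gt <- gt - w * (2 / (nt^2 * s)) * (rowSums(Ktt) * ft - Ktt %*% ft)
    # cross term: -c/(ns*nt) * sum_ij Kst[i,j]; d/dx_i brings +c/(ns*nt*s)
    gs <- gs + w * (cross_coefficient / (ns * nt * s)) *
      (rowSums(Kst) * fs - Kst %*% ft)
    gt <- gt + w * (cross_coefficient / (ns * nt * s)) *
      (colSums(Kst) * ft - crossprod(Kst, fs))
  }
  list(source = gs, target = gt)
}

#' Median-heuristic kernel bank
#'
#' Centers the bank at the median pairwise squared distance of the pooled
#' source and target features and spaces the remaining bandwidths
#' geometrically and symmetrically around it, with equal weights. The
#' original formulation leaves the bandwidths unspecified; this is the
#' standard multi-kernel MMD choice.
#'
#' @param features_s,features_t feature matrices `[n, d]`.
#' @param n_kernels number of RBF kernels (default 5).
#' @param spacing multiplicative spacing between consecutive bandwidths
#'   (default 2).
#' @return A [kernel_bank()].
#' @export
median_heuristic_bank <- function(features_s, features_t, n_kernels = 5L,
                                  spacing = 2) {
  if (is.null(dim(features_s))) features_s <- matrix(features_s, nrow = 1)
  if (is.null(dim(features_t))) features_t <- matrix(features_t, nrow = 1)
  pooled <- rbind(features_s, features_t)
  if (nrow(pooled) < 2) stop("need at least 2 pooled points")
  med <- median(stats::dist(pooled)^2)
  if (med == 0) stop("all pooled points identical: zero median distance")
  expo <- seq_len(n_kernels) - (n_kernels + 1) / 2
  kernel_bank(med * spacing^expo)
}

#' Source-domain classification loss
#'
#' Mean negative log-probability of the true class under the classifier's
#' softmax output, computed on labelled source samples only.
#'
#' @param probs `[n, M]` matrix of class probabilities (rows sum to 1).
#' @param labels integer class labels in `1..M`.
#' @param floor probability clamp applied before the log.
#' @return Scalar cross-entropy in nats.
#' @export
classification_loss <- function(probs, labels, floor = 1e-12) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs))
    stop("one label per probability row required")
  if (any(labels < 1L | labels > ncol(probs)))
    stop("label out of range 1..", ncol(probs))
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, floor)))
}

#' Domain-prediction cross-entropy
#'
#' Mean cross-entropy `H` of the domain discriminator's predictions over
#' the joint source + target batch. In the two-level objective the
#' adversarial term enters the generator as `L_D = -H` (the generator is
#' rewarded for confusing the discriminator) while the discriminator step
#' minimizes `H` itself; this function returns `H`.
#'
#' @param probs `[n, N]` matrix of domain probabilities.
#' @param domains integer domain labels in `1..N`.
#' @inheritParams classification_loss
#' @return Scalar cross-entropy `H` in nats.
#' @export
domain_adversarial_loss <- function(probs, domains, floor = 1e-12) {
  classification_loss(probs, domains, floor)
}

#' Discriminator gradient penalty
#'
#' Mean over evaluation points of `(||grad_x s(x)||_2 - 1)^2`, where `s`
#' is the discriminator's penalized scalar (the pre-softmax source-class
#' logit). Input gradients must be exact (analytic or automatic); there
#' is deliberately no finite-difference fallback.
#'
#' @param disc either a trained discriminator head (class `dense_head`)
#'   or a list with element `grad`, a function mapping an `[k, d]` matrix
#'   of evaluation points to the `[k, d]` matrix of input gradients of
#'   the penalized scalar.
#' @param eval_points `[k, d]` matrix of points at which the constraint
#'   is enforced.
#' @return Scalar penalty (to be scaled by `lambda_L` by the caller).
#' @export
gradient_penalty <- function(disc, eval_points) {
  eval_points <- as.matrix(eval_points)
  g <- if (inherits(disc, "dense_head")) {
    # softmax logit of class 1 is linear: gradient is the weight row
    matrix(disc$W[, 1], nrow(eval_points), nrow(disc$W), byrow = TRUE)
  } else if (is.list(disc) && is.function(disc$grad)) {
    as.matrix(disc$grad(eval_points))
  } else {
    stop("no exact input-gradient available for this discriminator")
  }
  if (!all(dim(g) == dim(eval_points)))
    stop("gradient shape does not match evaluation points")
  norms <- sqrt(rowSums(g^2))
  mean((norms - 1)^2)
}

#' Combined generator/classifier objective
#'
#' `L_G = L_C + lambda_d * L_D + lambda_m * L_MMD + lambda_z * ||W||^2`
#' with `L_D = -H` (domain confusion) and `||W||^2` the summed squared
#' dense-layer weights of the generator and classifier.
#'
#' @param l_c classification loss.
#' @param h domain cross-entropy from [domain_adversarial_loss()].
#' @param l_mmd squared MMD.
#' @param w2 summed squared weights.
#' @param lambda_d,lambda_m,lambda_z loss weights.
#' @return Scalar `L_G`.
#' @export
generator_objective <- function(l_c, h, l_mmd, w2,
                                lambda_d = 0.1, lambda_m = 0.1,
                                lambda_z = 0.01) {
  stopifnot(is.finite(l_c), is.finite(h), is.finite(l_mmd), is.finite(w2))
  l_c + lambda_d * (-h) + lambda_m * l_mmd + lambda_z * w2
}

#' Discriminator objective
#'
#' The discriminator step minimizes the domain cross-entropy plus the
#' Lipschitz gradient penalty: `H + lambda_L * GP`.
#'
#' @param h domain cross-entropy.
#' @param gp gradient penalty from [gradient_penalty()].
#' @param lambda_L penalty weight.
#' @return Scalar objective.
#' @export
discriminator_objective <- function(h, gp, lambda_L = 10) {
  stopifnot(is.finite(h), is.finite(gp))
  h + lambda_L * gp
}
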