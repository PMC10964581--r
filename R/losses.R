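#' @title Segmentation losses
#' @name losses
#' @description
#' The loss functions used by the HFS-Net sub-models and their ablation grid:
#' cross entropy, soft-dice loss, focal loss, median-frequency-balanced focal
#' loss, and weighted sums of these (e.g. `"ce+dice"`, `"focal+dice"`).
#' Probabilities are arrays whose last dimension indexes classes and sums to 1
#' per voxel; targets are integer arrays of class ids in `1..K` with the same
#' spatial shape.
NULL

.EPS <- 1e-7

clamp_probs <- function(p) pmin(pmax(p, .EPS), 1 - .EPS)

# spatial shape / class count helpers
.nclass <- function(probs) dim(probs)[length(dim(probs))]

.check_probs_target <- function(probs, target) {
  dp <- dim(probs)
  if (is.null(dp) || length(dp) < 2)
    stop2("probs must be an array with a trailing class dimension")
  sp <- dp[-length(dp)]
  dt <- dim(target) %||% length(target)
  if (!identical(as.integer(sp), as.integer(dt)))
    stop2("target spatial shape (%s) does not match probs (%s)",
          paste(dt, collapse = "x"), paste(sp, collapse = "x"))
  K <- dp[length(dp)]
  if (any(target < 1L | target > K))
    stop2("target class ids must lie in 1..%d", K)
  invisible(K)
}

# probability of the true class at every voxel, as a vector
.p_true <- function(probs, target) {
  K <- .nclass(probs)
  n <- length(target)
  pm <- matrix(probs, nrow = n, ncol = K)
  pm[cbind(seq_len(n), as.integer(target))]
}

#' Cross-entropy loss
#'
#' Mean negative log-likelihood of the true class over voxels. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param probs numeric array `(..., K)` of per-voxel class probabilities.
#' @param target integer array of class ids in `1..K`.
#' @param class_weights optional per-class weight vector of length `K`.
#' @return nonnegative scalar.
#' @examples
#' p <- array(0.5, c(2, 2, 2))
#' t <- matrix(1L, 2, 2)
#' cross_entropy(p, t) # log(2)
#' @export
cross_entropy <- function(probs, target, class_weights = NULL) {
  K <- .check_probs_target(probs, target)
  pt <- clamp_probs(.p_true(probs, target))
  w <- if (is.null(class_weights)) 1 else class_weights[as.integer(target)]
  mean(-w * log(pt))
}

# gradient of cross_entropy w.r.t. probs (same shape as probs).
# NOTE: gradients use the un-clamped probability (floored only at 1e-300):
# chaining -1/p_t through the softmax then yields the exact bounded
# (p - y)/n logit gradient. Clamping here at 1e-7 would annihilate the
# gradient once the softmax saturates and make a collapse inescapable.
cross_entropy_grad <- function(probs, target, class_weights = NULL) {
  K <- .nclass(probs)
  n <- length(target)
  pt <- pmax(.p_true(probs, target), 1e-300)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[as.integer(target)]
  g <- matrix(0, n, K)
  g[cbind(seq_len(n), as.integer(target))] <- -w / (pt * n)
  array(g, dim(probs))
}

#' Soft-dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` on the foreground
#' probability map, with additive smoothing `s` in numerator and denominator.
#' Lies in `[0, 1]`.
#'
#' @inheritParams cross_entropy
#' @param fg_class which class id is foreground (default: the last class).
#' @param smooth additive smoothing term (default 1).
#' @export
dice_loss <- function(probs, target, fg_class = NULL, smooth = 1) {
  K <- .check_probs_target(probs, target)
  fg <- fg_class %||% K
  n <- length(target)
  p <- matrix(probs, n, K)[, fg]
  t <- as.numeric(target == fg)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

dice_loss_grad <- function(probs, target, fg_class = NULL, smooth = 1) {
  K <- .nclass(probs)
  fg <- fg_class %||% K
  n <- length(target)
  p <- matrix(probs, n, K)[, fg]
  t <- as.numeric(target == fg)
  num <- 2 * sum(p * t) + smooth
  den <- sum(p) + sum(t) + smooth
  dp <- -(2 * t * den - num) / den^2
  g <- matrix(0, n, K)
  g[, fg] <- dp
  array(g, dim(probs))
}

#' Focal loss
#'
#' Mean of `-w_c * (1 - p_t)^gamma * log(p_t)` over voxels, where `p_t` is the
#' probability assigned to the true class. Reduces to (weighted) cross entropy
#' at `gamma = 0`.
#'
#' @inheritParams cross_entropy
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @export
focal_loss <- function(probs, target, gamma = 2, class_weights = NULL) {
  if (gamma < 0) stop2("gamma must be >= 0")
  .check_probs_target(probs, target)
  pt <- clamp_probs(.p_true(probs, target))
  w <- if (is.null(class_weights)) 1 else class_weights[as.integer(target)]
  mean(-w * (1 - pt)^gamma * log(pt))
}

focal_loss_grad <- function(probs, target, gamma = 2, class_weights = NULL) {
  K <- .nclass(probs)
  n <- length(target)
  pt <- pmax(.p_true(probs, target), 1e-300)  # un-clamped; see cross_entropy_grad
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[as.integer(target)]
  # d/dp [-(1-p)^g log p] = g (1-p)^(g-1) log p - (1-p)^g / p
  d <- if (gamma == 0) -1 / pt else
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  g <- matrix(0, n, K)
  g[cbind(seq_len(n), as.integer(target))] <- w * d / n
  array(g, dim(probs))
}

#' Median-frequency-balance class weights
#'
#' `weight_c = median(frequencies) / frequency_c`, the reweighting used by the
#' median-frequency-balanced focal loss so that rare classes (small tumors)
#' are not swamped by background voxels.
#'
#' @param class_frequencies positive per-class voxel frequencies summing to 1.
#' @return per-class weight vector.
#' @examples
#' mfb_weights(c(0.9, 0.1)) # c(0.5556, 5)
#' @export
mfb_weights <- function(class_frequencies) {
  f <- class_frequencies
  if (any(f <= 0))
    stop2("class frequency is zero for class(es) %s: class absent from training set",
          paste(which(f <= 0), collapse = ", "))
  if (abs(sum(f) - 1) > 1e-6) stop2("class frequencies must sum to 1")
  stats::median(f) / f
}

#' Loss specification
#'
#' Describes a (possibly compound) loss as a weighted sum of terms. Terms are
#' `"ce"`, `"dice"`, `"focal"` and `"mfb_focal"`; compound specs are written
#' `"ce+dice"`, `"focal+dice"` etc. with unit term weights.
#'
#' @param terms character vector of term names, or a single `"a+b"` string.
#' @param weights per-term positive multipliers (recycled; default 1).
#' @param focal_gamma focusing exponent for focal terms (default 2).
#' @param class_weights optional per-class weights; for `"mfb_focal"` these are
#'   normally filled in from training-set class frequencies via [mfb_weights()].
#' @return an object of class `loss_spec`.
#' @examples
#' loss_spec("focal+dice")
#' @export
loss_spec <- function(terms, weights = 1, focal_gamma = 2, class_weights = NULL) {
  if (length(terms) == 1 && grepl("+", terms, fixed = TRUE))
    terms <- strsplit(terms, "+", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  known <- c("ce", "dice", "focal", "mfb_focal")
  bad <- setdiff(terms, known)
  if (length(bad)) stop2("unknown loss term(s): %s", paste(bad, collapse = ", "))
  if (length(terms) < 1) stop2("at least one loss term is required")
  weights <- rep_len(weights, length(terms))
  if (any(weights <= 0)) stop2("term weights must be positive")
  structure(list(terms = terms, weights = weights, focal_gamma = focal_gamma,
                 class_weights = class_weights),
            class = "loss_spec")
}

#' @export
format.loss_spec <- function(x, ...) paste(x$terms, collapse = "+")

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec> ", format(x), " (gamma=", x$focal_gamma, ")\n", sep = "")
  invisible(x)
}

#' Evaluate a compound loss
#'
#' Weighted sum of the term losses in a [loss_spec()]. With `grad = TRUE` also
#' returns the gradient with respect to `probs`, through every term.
#'
#' @param spec a [loss_spec()].
#' @inheritParams cross_entropy
#' @param grad also compute the gradient array.
#' @return scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
compound_loss <- function(spec, probs, target, grad = FALSE) {
  stopifnot(inherits(spec, "loss_spec"))
  cw <- spec$class_weights
  val <- 0
  g <- if (grad) array(0, dim(probs)) else NULL
  for (i in seq_along(spec$terms)) {
    w <- spec$weights[i]
    term <- spec$terms[i]
    val <- val + w * switch(term,
      ce = cross_entropy(probs, target, cw),
      dice = dice_loss(probs, target),
      focal = focal_loss(probs, target, spec$focal_gamma, NULL),
      mfb_focal = focal_loss(probs, target, spec$focal_gamma, cw))
    if (grad) {
      g <- g + w * switch(term,
        ce = cross_entropy_grad(probs, target, cw),
        dice = dice_loss_grad(probs, target),
        focal = focal_loss_grad(probs, target, spec$focal_gamma, NULL),
        mfb_focal = focal_loss_grad(probs, target, spec$focal_gamma, cw))
    }
  }
  if (grad) list(value = val, grad = g) else val
}
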