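#' Loss configuration for segmentation training
#'
#' The training objective is the hybrid `L = alpha * L_BCE + (1 - alpha) *
#' L_Dice`.  `alpha` balances pixel-wise accuracy (BCE) against region
#' overlap (Dice); `epsilon` is the Dice smoothing constant preventing
#' division by zero on empty masks.
#'
#' @param alpha BCE weight in `[0, 1]`; default 0.5.
#' @param epsilon Dice smoothing constant, > 0; default 1e-6.
#' @export
loss_config <- function(alpha = 0.5, epsilon = 1e-6) {
  check_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  check_that(epsilon > 0, "epsilon must be positive")
  structure(list(alpha = alpha, epsilon = epsilon), class = "loss_config")
}

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-[y log(yhat) + (1 - y) log(1 - yhat)]`.
#' Predictions are clipped to `[clip, 1 - clip]` for numerical stability.
#'
#' @param y binary ground truth.
#' @param y_hat predicted probabilities in `(0, 1)`.
#' @param clip clipping distance from the 0/1 boundary.
#' @export
bce_loss <- function(y, y_hat, clip = 1e-7) {
  check_that(length(y) == length(y_hat), "shape mismatch between y and y_hat")
  p <- pmin(pmax(as.vector(y_hat), clip), 1 - clip)
  yv <- as.vector(y)
  -mean(yv * log(p) + (1 - yv) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(y * yhat) + eps) / (sum(y) + sum(yhat) + eps)`, pooling all
#' pixels of the batch as one set.  Both-empty input gives exactly 0
#' (`eps/eps = 1`).
#'
#' @param y binary ground truth.
#' @param y_hat predicted probabilities in `[0, 1]`.
#' @param epsilon smoothing constant.
#' @export
dice_loss <- function(y, y_hat, epsilon = 1e-6) {
  check_that(length(y) == length(y_hat), "shape mismatch between y and y_hat")
  yv <- as.vector(y)
  pv <- as.vector(y_hat)
  1 - (2 * sum(yv * pv) + epsilon) / (sum(yv) + sum(pv) + epsilon)
}

#' Hybrid Dice + BCE loss
#'
#' Exact affine combination `alpha * bce_loss + (1 - alpha) * dice_loss`.
#'
#' @inheritParams dice_loss
#' @param cfg a [loss_config()].
#' @export
hybrid_loss <- function(y, y_hat, cfg = loss_config()) {
  cfg$alpha * bce_loss(y, y_hat) + (1 - cfg$alpha) * dice_loss(y, y_hat, cfg$epsilon)
}

# Gradient of the hybrid loss w.r.t. the predicted probabilities.
# BCE term: d/dp -mean(...) = (p - y) / (p (1 - p) N) on the clipped region;
# Dice term from the quotient rule on the pooled soft Dice.
hybrid_loss_grad <- function(y, y_hat, cfg, clip = 1e-7) {
  yv <- as.vector(y)
  pv <- as.vector(y_hat)
  n <- length(pv)
  pc <- pmin(pmax(pv, clip), 1 - clip)
  g_bce <- (pc - yv) / (pc * (1 - pc)) / n
  g_bce[pv < clip | pv > 1 - clip] <- 0
  num <- 2 * sum(yv * pv) + cfg$epsilon
  den <- sum(yv) + sum(pv) + cfg$epsilon
  g_dice <- -(2 * yv * den - num) / den^2
  g <- cfg$alpha * g_bce + (1 - cfg$alpha) * g_dice
  array(g, dim = dim(y_hat) %||% length(y_hat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
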