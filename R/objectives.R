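#' Class-weighted soft Dice loss
#'
#' For a batch of P samples the loss is
#' \deqn{L_D = -\frac{1}{P}\sum_p \sum_l w_l
#'   \frac{2\sum_i y_p^l(i)\,\hat y_p^l(i)}
#'        {\sum_i (y_p^l(i) + \hat y_p^l(i)) + \epsilon}}
#' i.e. the negative weighted mean soft Dice overlap, bounded in
#' \eqn{[-1, 0]} when the weights sum to 1. The stabiliser \eqn{\epsilon}
#' appears in the denominator only, so a class absent from both reference
#' and prediction contributes 0 (a zero numerator), not a perfect score.
#' References may be soft (block-averaged) masks.
#'
#' @param y,yhat Numeric arrays of identical shape: `(H, W, K)` for one
#'   sample or `(H, W, K, P)` for a batch (any spatial shape; classes on
#'   the second-to-last margin).
#' @param weights Per-class weights `w_l` (default from [label_set()]).
#' @param eps Denominator stabiliser \eqn{\epsilon} (default `1e-5`).
#' @return Scalar loss.
#' @export
dice_loss <- function(y, yhat, weights = label_set()$weights, eps = 1e-5) {
  z <- check_loss_shapes(y, yhat, weights)
  total <- 0
  for (p in seq_len(z$P)) {
    yp <- matrix(z$y[, , p], ncol = length(z$w))
    hp <- matrix(z$yhat[, , p], ncol = length(z$w))
    num <- 2 * colSums(yp * hp)
    den <- colSums(yp) + colSums(hp) + eps
    total <- total + sum(z$w * num / den)
  }
  -total / z$P
}

#' Gradient of [dice_loss()] with respect to the predictions
#' @inheritParams dice_loss
#' @return Array of the same shape as `yhat`.
#' @export
dice_loss_grad <- function(y, yhat, weights = label_set()$weights,
                           eps = 1e-5) {
  z <- check_loss_shapes(y, yhat, weights)
  g <- array(0, dim = dim(z$yhat))
  for (p in seq_len(z$P)) {
    yp <- matrix(z$y[, , p], ncol = length(z$w))
    hp <- matrix(z$yhat[, , p], ncol = length(z$w))
    num <- 2 * colSums(yp * hp)
    den <- colSums(yp) + colSums(hp) + eps
    # d/dh_i [num/den] = (2 y_i den - num) / den^2
    g[, , p] <- -sweep(
      sweep(2 * yp, 2, den, "*") - matrix(num, nrow(yp), length(num),
                                          byrow = TRUE),
      2, z$w / (den^2), "*") / z$P
  }
  array(g, dim = dim(yhat))
}

#' Per-class specificity loss
#'
#' The negative average pixel specificity of a batch:
#' \deqn{L_S = -\frac{1}{P}\sum_p \sum_l w_l
#'   \frac{\sum_i (1-y_p^l(i))(1-\hat y_p^l(i))}
#'        {\sum_i (1-\hat y_p^l(i)) + \epsilon}}
#' Used in the checkpoint-selection metric to penalise false positives.
#'
#' @inheritParams dice_loss
#' @return Scalar loss in `[-1, 0]` for weights summing to 1.
#' @export
specificity_loss <- function(y, yhat, weights = label_set()$weights,
                             eps = 1e-5) {
  z <- check_loss_shapes(y, yhat, weights)
  total <- 0
  for (p in seq_len(z$P)) {
    yp <- matrix(z$y[, , p], ncol = length(z$w))
    hp <- matrix(z$yhat[, , p], ncol = length(z$w))
    num <- colSums((1 - yp) * (1 - hp))
    den <- colSums(1 - hp) + eps
    total <- total + sum(z$w * num / den)
  }
  -total / z$P
}

#' Gradient of [specificity_loss()] with respect to the predictions
#' @inheritParams dice_loss
#' @return Array of the same shape as `yhat`.
#' @export
specificity_loss_grad <- function(y, yhat, weights = label_set()$weights,
                                  eps = 1e-5) {
  z <- check_loss_shapes(y, yhat, weights)
  g <- array(0, dim = dim(z$yhat))
  for (p in seq_len(z$P)) {
    yp <- matrix(z$y[, , p], ncol = length(z$w))
    hp <- matrix(z$yhat[, , p], ncol = length(z$w))
    num <- colSums((1 - yp) * (1 - hp))
    den <- colSums(1 - hp) + eps
    # d/dh_i [num/den] = (-(1-y_i) den + num) / den^2
    g[, , p] <- -sweep(
      -sweep(1 - yp, 2, den, "*") + matrix(num, nrow(yp), length(num),
                                           byrow = TRUE),
      2, z$w / (den^2), "*") / z$P
  }
  array(g, dim = dim(yhat))
}

#' Checkpoint-selection metric V
#'
#' `V = alpha * L_D + (1 - alpha) * L_S`: a convex combination of the soft
#' Dice loss and the specificity loss, evaluated on a validation set to
#' pick network weights after training. `alpha = 1` reduces exactly to the
#' Dice loss.
#'
#' @inheritParams dice_loss
#' @param alpha Balance in `[0, 1]`.
#' @return Scalar metric (lower is better).
#' @export
selection_metric <- function(y, yhat, alpha,
                             weights = label_set()$weights, eps = 1e-5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (alpha == 1) return(dice_loss(y, yhat, weights, eps))
  if (alpha == 0) return(specificity_loss(y, yhat, weights, eps))
  alpha * dice_loss(y, yhat, weights, eps) +
    (1 - alpha) * specificity_loss(y, yhat, weights, eps)
}

check_loss_shapes <- function(y, yhat, weights) {
  if (!identical(dim(y), dim(yhat))) {
    stop("y and yhat must have identical shapes")
  }
  d <- dim(y)
  if (is.null(d)) stop("y and yhat must be arrays with a class margin")
  nd <- length(d)
  if (nd == 2) {  # (pixels, classes)
    K <- d[2]
    P <- 1L
    npx <- d[1]
  } else if (nd == 3) {  # (H, W, K)
    K <- d[3]
    P <- 1L
    npx <- d[1] * d[2]
  } else if (nd == 4) {  # (H, W, K, P)
    K <- d[3]
    P <- d[4]
    npx <- d[1] * d[2]
  } else {
    stop("unsupported array rank: ", nd)
  }
  if (length(weights) != K) {
    stop("weights length (", length(weights),
         ") does not match class count (", K, ")")
  }
  list(y = array(y, dim = c(npx, K, P)),
       yhat = array(yhat, dim = c(npx, K, P)),
       w = weights, P = P)
}
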