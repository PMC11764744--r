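# Training loss components and the polynomial learning-rate schedule.

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(g * log(p) + (1 - g) * log(1 - p))`.
#' Probabilities are clipped to `[tau, 1 - tau]` for numerical safety.
#'
#' @param p Predicted foreground probabilities in `[0, 1]`.
#' @param g Binary ground truth of the same shape.
#' @param tau Clipping bound, default `1e-7`.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(p, g, tau = 1e-7) {
  check_same_shape(p, g)
  p <- pmin(pmax(p, tau), 1 - tau)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)`.  Two empty
#' masks give loss 0 (the smoothing term dominates).
#'
#' @inheritParams bce_loss
#' @param eps Smoothing term, default `1e-5`.
#' @return Loss in `[0, 1]`.
#' @export
dice_loss <- function(p, g, eps = 1e-5) {
  check_same_shape(p, g)
  1 - (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)
}

#' Composite segmentation loss
#'
#' `0.5 * BCE + Dice`.  Multi-class inputs (arrays whose third dimension
#' indexes classes) are averaged over classes.
#'
#' @inheritParams dice_loss
#' @export
composite_loss <- function(p, g, eps = 1e-5) {
  check_same_shape(p, g)
  d <- dim(p)
  if (!is.null(d) && length(d) >= 3 && d[3] > 1) {
    per_class <- vapply(seq_len(d[3]), function(c) {
      pc <- index_class(p, c); gc <- index_class(g, c)
      0.5 * bce_loss(pc, gc) + dice_loss(pc, gc, eps)
    }, 0)
    return(mean(per_class))
  }
  0.5 * bce_loss(p, g) + dice_loss(p, g, eps)
}

index_class <- function(a, c) {
  d <- dim(a)
  if (length(d) == 3) a[, , c] else a[, , c, ]
}

check_same_shape <- function(p, g) {
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop("prediction and ground truth must have identical shapes")
  invisible(NULL)
}

#' Polynomial learning-rate decay
#'
#' `eta(epoch) = eta_init * (1 - epoch / num_epochs)^power`; strictly
#' decreasing in the epoch, reaching exactly 0 at `num_epochs`.
#'
#' @param epoch Current epoch index, `0 <= epoch <= num_epochs`.
#' @param eta_init Initial learning rate (default `1e-3`).
#' @param num_epochs Total epochs (default 150).
#' @param power Decay exponent (default 0.9).
#' @return The learning rate for `epoch`.
#' @export
poly_lr <- function(epoch, eta_init = 1e-3, num_epochs = 150L, power = 0.9) {
  if (power <= 0) stop("power must be positive")
  if (epoch < 0 || epoch > num_epochs)
    stop("epoch must be in [0, num_epochs]")
  eta_init * (1 - epoch / num_epochs)^power
}
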