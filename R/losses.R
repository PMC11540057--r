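#' Loss configuration
#'
#' @param epsilon smoothing constant of the soft-Dice term, preventing
#'   division by zero (also makes the empty-vs-empty case a perfect 0 loss).
#' @param clip numerical floor applied to predictions inside the logarithms.
#' @param region_weights nonnegative weights for the WT, TC, ET channels.
#' @return a `loss_config` list.
#' @export
loss_config <- function(epsilon = 1e-5, clip = 1e-7,
                        region_weights = c(1, 1, 1)) {
  stopifnot(epsilon > 0, clip > 0, all(region_weights >= 0))
  structure(list(epsilon = epsilon, clip = clip,
                 region_weights = region_weights), class = "loss_config")
}

check_loss_shapes <- function(u, v) {
  if (!identical(dim(u) %||% length(u), dim(v) %||% length(v)))
    stop_waveseg("waveseg_invalid_argument",
                 "target and prediction shapes differ")
}

#' Binary cross-entropy loss
#'
#' Voxelwise `-(u log v + (1 - u) log(1 - v))` averaged over all voxels and
#' region channels; predictions are clipped to `[clip, 1 - clip]` before the
#' logarithms.
#'
#' @param u binary target array.
#' @param v prediction array in `(0, 1)`, same shape.
#' @param clip numerical floor for the logarithm.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(u, v, clip = 1e-7) {
  check_loss_shapes(u, v)
  v <- pmin(pmax(v, clip), 1 - clip)
  -mean(u * log(v) + (1 - u) * log(1 - v))
}

#' Soft-Dice loss
#'
#' Per region channel `1 - (2 |u ∩ v| + eps) / (|u| + |v| + eps)` with the
#' soft intersection `sum(u * v)`, averaged over channels.  When both the
#' target and the prediction are empty the smoothing constant makes the loss
#' exactly 0.
#'
#' @param u binary target array; if 4D, the last axis indexes regions.
#' @param v soft prediction in `[0, 1]`, same shape.
#' @param epsilon smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(u, v, epsilon = 1e-5) {
  check_loss_shapes(u, v)
  R <- if (length(dim(u)) == 4) dim(u)[4] else 1L
  um <- matrix(u, ncol = R); vm <- matrix(v, ncol = R)
  per <- 1 - (2 * colSums(um * vm) + epsilon) /
             (colSums(um) + colSums(vm) + epsilon)
  mean(per)
}

#' Combined training loss
#'
#' `L = L_BCE + L_Dice`, the sum of [bce_loss()] and [dice_loss()].
#'
#' @inheritParams dice_loss
#' @param config a [loss_config()].
#' @return list with `total`, `bce` and `dice`.
#' @export
total_loss <- function(u, v, config = loss_config()) {
  b <- bce_loss(u, v, config$clip)
  d <- dice_loss(u, v, config$epsilon)
  list(total = b + d, bce = b, dice = d)
}

#' Analytic gradient of the combined loss
#'
#' Gradient of [total_loss()] with respect to the prediction array, computed
#' through the package's reverse-mode tape.  Mainly used to audit the
#' training objective against finite differences.
#'
#' @inheritParams total_loss
#' @return array of the same shape as `v`.
#' @export
total_loss_grad <- function(u, v, config = loss_config()) {
  node <- ad_leaf(v, requires_grad = TRUE)
  loss <- ad_bce_dice_loss(node, u, config$epsilon, config$clip)
  ad_backward(loss)
  array(node$grad, dim = dim(v) %||% length(v))
}
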