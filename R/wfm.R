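#' Fuse four subband sets: mean of lows, sum of highs
#'
#' The wavelet-domain fusion rule: the low-frequency `lll` coefficients carry
#' the overall appearance of each modality and are averaged; the seven
#' high-frequency subbands carry detail and are summed to accentuate it.
#' Alternative high-frequency rules (`"mean"`, `"max"`) are available behind
#' the `high_freq_rule` switch.
#'
#' @param subband_sets list of exactly four `subband_set`s with identical
#'   shapes and wavelet.
#' @param high_freq_rule one of `"sum"` (default), `"mean"`, `"max"`.
#' @return the fused `subband_set`.
#' @export
fuse_subbands <- function(subband_sets, high_freq_rule = c("sum", "mean", "max")) {
  high_freq_rule <- match.arg(high_freq_rule)
  if (length(subband_sets) != 4)
    stop_waveseg("waveseg_invalid_argument",
                 "expected exactly 4 subband sets, got %d", length(subband_sets))
  ref <- subband_sets[[1]]
  for (s in subband_sets) {
    stopifnot(inherits(s, "subband_set"))
    if (!identical(s$wavelet_name, ref$wavelet_name) ||
        !all(dim(s$lll) == dim(ref$lll)))
      stop_waveseg("waveseg_invalid_argument",
                   "subband sets differ in shape or wavelet")
  }
  fused <- ref
  fused$lll <- (subband_sets[[1]]$lll + subband_sets[[2]]$lll +
                subband_sets[[3]]$lll + subband_sets[[4]]$lll) / 4
  for (nm in SUBBAND_NAMES[-1]) {
    acc <- switch(high_freq_rule,
      sum = subband_sets[[1]][[nm]] + subband_sets[[2]][[nm]] +
            subband_sets[[3]][[nm]] + subband_sets[[4]][[nm]],
      mean = (subband_sets[[1]][[nm]] + subband_sets[[2]][[nm]] +
              subband_sets[[3]][[nm]] + subband_sets[[4]][[nm]]) / 4,
      max = pmax(subband_sets[[1]][[nm]], subband_sets[[2]][[nm]],
                 subband_sets[[3]][[nm]], subband_sets[[4]][[nm]]))
    fused[[nm]] <- acc
  }
  fused
}

#' Wavelet-domain fusion of four per-modality feature maps
#'
#' Computes `F = IDWT(f(DWT(X1), DWT(X2), DWT(X3), DWT(X4)))` channel-wise,
#' where `f` averages the low-frequency subband and combines the
#' high-frequency subbands under `high_freq_rule`.  The result has the same
#' shape as each input map; the operation has no trainable state.
#'
#' @param stack list of four `D x H x W x C` arrays (modality order T1, T1ce,
#'   T2, FLAIR), or a `4 x ...` list from the encoders.
#' @param wavelet wavelet identifier.
#' @param high_freq_rule high-frequency fusion rule, see [fuse_subbands()].
#' @return fused array of shape `D x H x W x C`.
#' @export
wavelet_fuse <- function(stack, wavelet = "haar",
                         high_freq_rule = c("sum", "mean", "max")) {
  high_freq_rule <- match.arg(high_freq_rule)
  check_feature_stack(stack)
  C <- dim(stack[[1]])[4]
  fused <- lapply(seq_len(C), function(ch) {
    sets <- lapply(stack, function(x)
      dwt3(array(x[, , , ch], dim = dim(x)[1:3]), wavelet))
    idwt3(fuse_subbands(sets, high_freq_rule))
  })
  array(unlist(fused, use.names = FALSE),
        dim = c(dim(fused[[1]]), C))
}

#' Wavelet fusion module forward pass
#'
#' The full module: the shared fused map `F` from [wavelet_fuse()] is added
#' elementwise to every modality's features (`Xi' = Xi + F`) and the four
#' residual-enhanced maps are concatenated along the channel axis in the
#' fixed modality order, giving `4C` output channels.
#'
#' @inheritParams wavelet_fuse
#' @return array of shape `D x H x W x 4C`.
#' @export
wfm_forward <- function(stack, wavelet = "haar",
                        high_freq_rule = c("sum", "mean", "max")) {
  high_freq_rule <- match.arg(high_freq_rule)
  check_feature_stack(stack)
  f <- wavelet_fuse(stack, wavelet, high_freq_rule)
  enhanced <- lapply(stack, function(x) x + f)
  d <- dim(stack[[1]])
  array(unlist(enhanced, use.names = FALSE),
        dim = c(d[1:3], 4L * d[4]))
}

check_feature_stack <- function(stack) {
  if (!is.list(stack) || length(stack) != 4)
    stop_waveseg("waveseg_invalid_argument",
                 "feature stack must be a list of 4 modality maps")
  d <- dim(stack[[1]])
  if (length(d) != 4)
    stop_waveseg("waveseg_invalid_argument",
                 "each modality map must be a D x H x W x C array")
  for (x in stack)
    if (!all(dim(x) == d))
      stop_waveseg("waveseg_invalid_argument",
                   "all four modality maps must share one shape")
  invisible(TRUE)
}
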