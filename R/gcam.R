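#' Initialise global-context attention parameters
#'
#' Creates the parameter set of the global context-aware block for `C`
#' channels: a 1x1x1 key map `C -> 1`, a bottleneck transform
#' `C -> C/r -> C` with layer normalisation over the `C/r` bottleneck, and
#' the bottleneck ratio `r`.  The output transform is zero-initialised by
#' default so the block starts as an exact identity, which stabilises early
#' training.
#'
#' @param channels number of feature channels `C`.
#' @param ratio bottleneck ratio `r`; the bottleneck width is
#'   `max(1, C %/% r)`.
#' @param zero_init logical; zero-initialise the output transform.
#' @param seed integer seed for the random initialisation.
#' @return a `gcam_params` list.
#' @export
gcam_params <- function(channels, ratio = 4L, zero_init = TRUE, seed = 1L) {
  if (ratio < 1)
    stop_waveseg("waveseg_config", "bottleneck ratio must be >= 1")
  M <- max(1L, channels %/% as.integer(ratio))
  with_seed(seed, {
    structure(list(
      key_w = matrix(rnorm(channels, sd = sqrt(1 / channels)), channels, 1),
      key_b = 0,
      w1 = matrix(rnorm(channels * M, sd = sqrt(2 / channels)), channels, M),
      b1 = numeric(M),
      ln_gamma = rep(1, M),
      ln_beta = numeric(M),
      w2 = if (zero_init) matrix(0, M, channels)
           else matrix(rnorm(M * channels, sd = sqrt(2 / M)), M, channels),
      b2 = numeric(channels),
      ratio = as.integer(ratio),
      channels = as.integer(channels)), class = "gcam_params")
  })
}

#' Global attention pooling over all spatial positions
#'
#' Computes one context vector per volume: attention logits are produced by
#' the 1x1x1 key map at every spatial position, turned into weights by a
#' softmax over all `N = D*H*W` positions, and used to average the feature
#' vectors.  The weights are nonnegative and sum to one.
#'
#' @param s feature array `D x H x W x C`.
#' @param key_w key weights, length-`C` vector or `C x 1` matrix.
#' @param key_b scalar key bias.
#' @return list with `context` (length-`C` vector) and `weights`
#'   (length-`N` softmax weights).
#' @export
context_pool <- function(s, key_w, key_b = 0) {
  d <- dim(s)
  stopifnot(length(d) == 4)
  N <- prod(d[1:3]); C <- d[4]
  S <- matrix(s, N, C)
  logits <- as.numeric(S %*% matrix(key_w, C, 1)) + key_b
  w <- exp(logits - max(logits))
  w <- w / sum(w)
  list(context = as.numeric(crossprod(S, w)), weights = w)
}

# Layer normalisation of a single vector.
layernorm_vec <- function(v, gamma, beta, eps = 1e-5) {
  mu <- mean(v)
  va <- mean((v - mu)^2)
  gamma * (v - mu) / sqrt(va + eps) + beta
}

#' Global context-aware block forward pass
#'
#' The three stages of the block: (a) context modelling by global attention
#' pooling ([context_pool()]); (b) a bottleneck transform
#' `Conv1x1x1(ReLU(LayerNorm(Conv1x1x1(context))))` acting on the pooled
#' `C`-vector; (c) fusion, broadcasting the transformed vector additively to
#' every spatial position.  The update is spatially constant per channel, so
#' the output minus the input has spatial rank zero.
#'
#' @param s feature array `D x H x W x C`.
#' @param params a `gcam_params` for `C` channels.
#' @return array of the same shape as `s`.
#' @export
gcam_forward <- function(s, params) {
  stopifnot(inherits(params, "gcam_params"))
  d <- dim(s)
  if (d[4] != params$channels)
    stop_waveseg("waveseg_config",
                 "params built for %d channels, input has %d",
                 params$channels, d[4])
  ctx <- context_pool(s, params$key_w, params$key_b)$context
  h <- as.numeric(ctx %*% params$w1) + params$b1
  h <- layernorm_vec(h, params$ln_gamma, params$ln_beta)
  h <- pmax(h, 0)
  l_trans <- as.numeric(h %*% params$w2) + params$b2
  sweep(s, 4, l_trans, `+`)
}

#' Exact parameter count of one global-context block
#'
#' @param channels number of channels `C`.
#' @param ratio bottleneck ratio `r`.
#' @return integer parameter count:
#'   `C + 1 + C*M + M + 2*M + M*C + C` with `M = max(1, C %/% r)`.
#' @export
gcam_param_count <- function(channels, ratio = 4L) {
  M <- max(1L, channels %/% as.integer(ratio))
  channels + 1L + channels * M + M + 2L * M + M * channels + channels
}
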