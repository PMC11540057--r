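#' Model configuration
#'
#' Hyperparameters of the five-level multi-encoder/single-decoder network.
#' Each of the four modalities has its own encoder (no weight sharing);
#' per-level encoder outputs are fused by the wavelet fusion module, reduced
#' by a 1x1x1 convolution, and fed to the single decoder as skip connections
#' (levels 1-4) or the bottleneck (level 5).  Global-context attention blocks
#' sit after the encoder residual blocks of the deep levels (default 4 and 5).
#'
#' @param base_channels channels at level 1; the schedule doubles per level.
#' @param num_levels number of resolution levels (5).
#' @param gcam_levels levels that carry a global-context block.
#' @param gcam_ratio bottleneck ratio of the global-context blocks.
#' @param wavelet wavelet family used by the fusion module.
#' @param high_freq_rule high-frequency fusion rule (`"sum"` or `"mean"`).
#' @param norm_groups group count for group normalisation (clamped to the
#'   channel count; group statistics make the model batch-size-1 safe).
#' @param out_regions number of sigmoid output channels (WT, TC, ET).
#' @return a `model_config` list.
#' @export
model_config <- function(base_channels = 16L, num_levels = 5L,
                         gcam_levels = c(4L, 5L), gcam_ratio = 4L,
                         wavelet = "haar", high_freq_rule = "sum",
                         norm_groups = 8L, out_regions = 3L) {
  if (num_levels < 1) stop_waveseg("waveseg_config", "num_levels must be >= 1")
  schedule <- as.integer(base_channels * 2^(seq_len(num_levels) - 1))
  structure(list(base_channels = as.integer(base_channels),
                 channel_schedule = schedule,
                 num_levels = as.integer(num_levels),
                 gcam_levels = as.integer(gcam_levels),
                 gcam_ratio = as.integer(gcam_ratio),
                 wavelet = wavelet,
                 high_freq_rule = high_freq_rule,
                 norm_groups = as.integer(norm_groups),
                 out_regions = as.integer(out_regions)),
            class = "model_config")
}

conv_init <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

res_block_params <- function(cin, cout, prefix) {
  p <- list()
  p[[paste0(prefix, ".conv1.w")]] <- conv_init(3, cin, cout)
  p[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  p[[paste0(prefix, ".gn1.gamma")]] <- rep(1, cout)
  p[[paste0(prefix, ".gn1.beta")]] <- numeric(cout)
  p[[paste0(prefix, ".conv2.w")]] <- conv_init(3, cout, cout)
  p[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  p[[paste0(prefix, ".gn2.gamma")]] <- rep(1, cout)
  p[[paste0(prefix, ".gn2.beta")]] <- numeric(cout)
  if (cin != cout) {
    p[[paste0(prefix, ".proj.w")]] <- conv_init(1, cin, cout)
    p[[paste0(prefix, ".proj.b")]] <- numeric(cout)
  }
  p
}

gcam_block_params <- function(C, ratio, prefix, zero_init = TRUE) {
  M <- max(1L, C %/% ratio)
  p <- list()
  p[[paste0(prefix, ".key.w")]] <- matrix(rnorm(C, sd = sqrt(1 / C)), C, 1)
  p[[paste0(prefix, ".key.b")]] <- 0
  p[[paste0(prefix, ".t1.w")]] <- matrix(rnorm(C * M, sd = sqrt(2 / C)), C, M)
  p[[paste0(prefix, ".t1.b")]] <- numeric(M)
  p[[paste0(prefix, ".ln.gamma")]] <- rep(1, M)
  p[[paste0(prefix, ".ln.beta")]] <- numeric(M)
  p[[paste0(prefix, ".t2.w")]] <- if (zero_init) matrix(0, M, C)
                                  else matrix(rnorm(M * C, sd = sqrt(2 / M)), M, C)
  p[[paste0(prefix, ".t2.b")]] <- numeric(C)
  p
}

#' Initialise network weights
#'
#' He-normal initialisation for convolutions, unit/zero group-norm affine
#' parameters, and zero-initialised global-context output transforms (so each
#' attention block starts as an exact identity).
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @param gcam_zero_init zero-initialise the attention output transforms
#'   (default `TRUE`; set `FALSE` to make every attention parameter active
#'   from the first step, e.g. for gradient-connectivity audits).
#' @return named list of parameter arrays.
#' @export
init_model <- function(config, seed = 1L, gcam_zero_init = TRUE) {
  stopifnot(inherits(config, "model_config"))
  cs <- config$channel_schedule
  L <- config$num_levels
  with_seed(seed, {
    p <- list()
    for (e in seq_len(4)) {
      cin <- 1L
      for (l in seq_len(L)) {
        pre <- sprintf("enc%d.l%d", e, l)
        p <- c(p, res_block_params(cin, cs[l], paste0(pre, ".res")))
        if (l %in% config$gcam_levels)
          p <- c(p, gcam_block_params(cs[l], config$gcam_ratio,
                                      paste0(pre, ".gcam"), gcam_zero_init))
        if (l < L) {
          p[[paste0(pre, ".down.w")]] <- conv_init(3, cs[l], cs[l + 1])
          p[[paste0(pre, ".down.b")]] <- numeric(cs[l + 1])
          cin <- cs[l + 1]
        }
      }
    }
    for (l in seq_len(L)) {
      p[[sprintf("fuse.l%d.reduce.w", l)]] <- conv_init(1, 4L * cs[l], cs[l])
      p[[sprintf("fuse.l%d.reduce.b", l)]] <- numeric(cs[l])
    }
    if (L > 1)
      for (l in seq_len(L - 1))
        p <- c(p, res_block_params(cs[l + 1] + cs[l], cs[l],
                                   sprintf("dec.l%d.res", l)))
    p[["head.w"]] <- conv_init(1, cs[1], config$out_regions)
    p[["head.b"]] <- numeric(config$out_regions)
    p
  })
}

ad_res_block <- function(x, P, prefix, groups) {
  h <- ad_conv3d(x, P[[paste0(prefix, ".conv1.w")]],
                 P[[paste0(prefix, ".conv1.b")]])
  h <- ad_relu(ad_groupnorm(h, P[[paste0(prefix, ".gn1.gamma")]],
                            P[[paste0(prefix, ".gn1.beta")]], groups))
  h <- ad_conv3d(h, P[[paste0(prefix, ".conv2.w")]],
                 P[[paste0(prefix, ".conv2.b")]])
  h <- ad_relu(ad_groupnorm(h, P[[paste0(prefix, ".gn2.gamma")]],
                            P[[paste0(prefix, ".gn2.beta")]], groups))
  skip <- if (!is.null(P[[paste0(prefix, ".proj.w")]]))
    ad_conv3d(x, P[[paste0(prefix, ".proj.w")]],
              P[[paste0(prefix, ".proj.b")]])
  else x
  ad_add(h, skip)
}

ad_gcam_block <- function(x, P, prefix) {
  ad_gcam(x,
          P[[paste0(prefix, ".key.w")]], P[[paste0(prefix, ".key.b")]],
          P[[paste0(prefix, ".t1.w")]], P[[paste0(prefix, ".t1.b")]],
          P[[paste0(prefix, ".ln.gamma")]], P[[paste0(prefix, ".ln.beta")]],
          P[[paste0(prefix, ".t2.w")]], P[[paste0(prefix, ".t2.b")]])
}

# Core graph builder: `P` is a named list of ad_nodes (or plain arrays for
# inference), `x` a (D,H,W,4) array.  Returns the sigmoid-probability node.
net_graph <- function(P, x, config) {
  L <- config$num_levels
  cs <- config$channel_schedule
  groups <- config$norm_groups
  gmin <- function(C) if (C %% groups == 0) groups else 1L
  skips <- vector("list", L)
  branch <- vector("list", L)
  for (l in seq_len(L)) branch[[l]] <- vector("list", 4)
  for (e in seq_len(4)) {
    f <- ad_leaf(x[, , , e, drop = FALSE])
    for (l in seq_len(L)) {
      pre <- sprintf("enc%d.l%d", e, l)
      f <- ad_res_block(f, P, paste0(pre, ".res"), gmin(cs[l]))
      if (l %in% config$gcam_levels)
        f <- ad_gcam_block(f, P, paste0(pre, ".gcam"))
      branch[[l]][[e]] <- f
      if (l < L)
        f <- ad_conv3d(f, P[[paste0(pre, ".down.w")]],
                       P[[paste0(pre, ".down.b")]], stride = 2L)
    }
  }
  for (l in seq_len(L)) {
    fused <- ad_wfuse(branch[[l]], config$wavelet, config$high_freq_rule)
    enhanced <- lapply(branch[[l]], function(b) ad_add(b, fused))
    cat4 <- ad_concat(enhanced)
    skips[[l]] <- ad_conv3d(cat4, P[[sprintf("fuse.l%d.reduce.w", l)]],
                            P[[sprintf("fuse.l%d.reduce.b", l)]])
  }
  d <- skips[[L]]
  if (L > 1) {
    for (l in rev(seq_len(L - 1))) {
      up <- ad_upsample2(d)
      d <- ad_concat(list(up, skips[[l]]))
      d <- ad_res_block(d, P, sprintf("dec.l%d.res", l), gmin(cs[l]))
    }
  }
  logits <- ad_conv3d(d, P[["head.w"]], P[["head.b"]])
  list(logits = logits, probs = ad_sigmoid(logits))
}

#' Segmentation network forward pass
#'
#' Runs the multi-encoder network on one multimodal volume and returns the
#' three region probability maps (WT, TC, ET) together with the logits.
#' Spatial dimensions must be divisible by `2^(num_levels - 1)`.
#'
#' @param params named parameter list from [init_model()].
#' @param x numeric array `D x H x W x 4` (modality order T1, T1ce, T2,
#'   FLAIR).
#' @param config the [model_config()] the parameters were built with.
#' @return list with `probabilities` and `logits`, both
#'   `D x H x W x out_regions` arrays.
#' @export
net_forward <- function(params, x, config) {
  d <- dim(x)
  if (length(d) != 4 || d[4] != 4)
    stop_waveseg("waveseg_invalid_argument", "input must be D x H x W x 4")
  div <- 2^(config$num_levels - 1)
  if (any(d[1:3] %% div != 0))
    stop_waveseg("waveseg_shape",
                 "spatial dims (%s) must be divisible by %d",
                 paste(d[1:3], collapse = "x"), div)
  P <- lapply(params, ad_leaf)
  out <- net_graph(P, x, config)
  list(probabilities = ad_value(out$probs), logits = ad_value(out$logits))
}

#' Per-block parameter counts
#'
#' Enumerates every weight array of a model configuration and tabulates the
#' exact parameter counts per architectural block and in total.
#'
#' @param config a [model_config()].
#' @return a `data.frame` with columns `block` and `parameters`, plus the
#'   grand total in the `total` attribute.
#' @export
count_parameters <- function(config) {
  p <- init_model(config, seed = 1L)
  sizes <- vapply(p, length, numeric(1))
  block <- sub("\\.(w|b|gamma|beta)$", "", names(sizes))
  block <- sub("\\.(conv1|conv2|gn1|gn2|proj|key|t1|t2|ln)$", "", block)
  agg <- stats::aggregate(list(parameters = sizes), list(block = block), sum)
  agg <- agg[order(agg$block), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "total") <- sum(sizes)
  agg
}
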