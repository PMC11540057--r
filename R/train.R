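#' Polynomial learning-rate decay
#'
#' `lr_t = lr0 * (1 - t/T)^power`, evaluated at step `t` of `T`.
#'
#' @param lr0 initial learning rate.
#' @param t current step (0-based).
#' @param total total number of steps `T`.
#' @param power decay exponent.
#' @return the decayed learning rate.
#' @export
poly_lr <- function(lr0, t, total, power = 0.9) {
  lr0 * (1 - t / total)^power
}

#' Soft Dice coefficient per region channel
#'
#' Differentiable Dice computed on probabilistic predictions:
#' `2 sum(u v) / (sum(u) + sum(v))` per channel (with smoothing `epsilon`).
#'
#' @param u binary target array (`... x R` for `R` regions, or 3D).
#' @param v soft prediction of the same shape.
#' @param epsilon smoothing constant.
#' @return numeric vector of per-region soft Dice values.
#' @export
soft_dice <- function(u, v, epsilon = 1e-5) {
  R <- if (length(dim(u)) == 4) dim(u)[4] else 1L
  um <- matrix(u, ncol = R); vm <- matrix(v, ncol = R)
  (2 * colSums(um * vm) + epsilon) / (colSums(um) + colSums(vm) + epsilon)
}

adam_update <- function(params, grads, state, lr, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[nm]] <- m; state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

region_target <- function(labels) {
  rm <- encode_regions(labels)
  array(c(as.numeric(rm$wt), as.numeric(rm$tc), as.numeric(rm$et)),
        dim = c(dim(labels), 3))
}

load_training_cases <- function(data, config) {
  if (is.character(data)) {
    manifest <- read_manifest(data)
    data <- lapply(manifest$cases, function(cs) read_case(cs$dir, cs$case_id))
  }
  stopifnot(is.list(data), length(data) >= 1)
  if (config$normalize) data <- lapply(data, zscore_normalize)
  data
}

#' Train the segmentation network
#'
#' Seeded training loop: Adam with weight decay and polynomial learning-rate
#' decay, one volume per step, optional mirror-flip/intensity-shift
#' augmentation and random cropping, per-step CSV-ready logging, and
#' best-checkpoint selection on validation mean Dice when a validation split
#' is held out.
#'
#' @param data either a list of `multimodal_volume`s with labels, or the path
#'   to a `manifest.json` written by [generate_dataset()].
#' @param config a [train_config()].
#' @param log_path optional CSV path for the per-step training log.
#' @return a `waveseg_model`: list with `params` (best weights), `config`,
#'   `log` (data.frame), `final_params`, `best_val_dice` and `modalities`.
#' @export
train_model <- function(data, config = train_config(), log_path = NULL) {
  stopifnot(inherits(config, "train_config"))
  cases <- load_training_cases(data, config)
  n <- length(cases)
  if (config$validate && n >= 2) {
    sp <- split_dataset(seq_len(n), config$split_ratio, config$seed)
    train_idx <- unlist(sp$train); val_idx <- unlist(sp$val)
  } else {
    train_idx <- seq_len(n); val_idx <- integer(0)
  }
  params <- init_model(config$model, seed = config$seed)
  state <- list(t = 0, m = list(), v = list())
  total_steps <- config$epochs * length(train_idx)
  log <- vector("list", total_steps)
  best <- list(dice = -Inf, params = params)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_idx <- with_seed(config$seed + epoch,
                           sample(train_idx, length(train_idx)))
    for (ci in order_idx) {
      vol <- cases[[ci]]
      aug_seed <- config$seed + 7919L * epoch + 101L * ci
      if (config$augment)
        vol <- augment_volume(vol, config$flip_p, config$shift_factor,
                              seed = aug_seed)
      if (!is.null(config$crop_size) &&
          any(dim(vol$channels)[1:3] > config$crop_size))
        vol <- random_crop(vol, config$crop_size, seed = aug_seed + 1L)
      target <- region_target(vol$labels)
      P <- lapply(params, ad_leaf, requires_grad = TRUE)
      out <- net_graph(P, vol$channels, config$model)
      loss <- ad_bce_dice_loss_logits(out$logits, target,
                                      config$loss$epsilon, config$loss$clip)
      if (!is.finite(loss$value))
        stop_waveseg("waveseg_nan",
                     "non-finite loss at epoch %d step %d (case %s)",
                     epoch, step, vol$case_id)
      ad_backward(loss)
      grads <- lapply(P, function(p) p$grad)
      lr_t <- poly_lr(config$lr, step, total_steps, config$poly_power)
      upd <- adam_update(params, grads, state, lr_t, config$weight_decay)
      params <- upd$params; state <- upd$state
      step <- step + 1L
      parts <- attr(loss, "parts")
      log[[step]] <- data.frame(epoch = epoch, step = step, lr = lr_t,
                                loss = loss$value, bce = parts[["bce"]],
                                dice_loss = parts[["dice"]], val_dice = NA)
    }
    if (length(val_idx) > 0) {
      vd <- mean(vapply(val_idx, function(ci) {
        out <- net_forward(params, cases[[ci]]$channels, config$model)
        mean(soft_dice(region_target(cases[[ci]]$labels), out$probabilities))
      }, numeric(1)))
      log[[step]]$val_dice <- vd
      if (vd > best$dice) best <- list(dice = vd, params = params)
    }
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  structure(list(params = if (length(val_idx) > 0) best$params else params,
                 final_params = params,
                 best_val_dice = if (length(val_idx) > 0) best$dice else NA,
                 config = config, log = log, modalities = MODALITIES),
            class = "waveseg_model")
}

#' Save / load a trained model
#'
#' Checkpoints store the weights, the full configuration and the modality
#' order so a model can be reloaded and applied without ambiguity.
#'
#' @param model a `waveseg_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `waveseg_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "waveseg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "waveseg_model"))
    stop_waveseg("waveseg_io", "'%s' is not a waveseg checkpoint", path)
  model
}

#' Predict a segmentation for one multimodal volume
#'
#' Forward pass, per-region thresholding at `threshold`, and decoding of the
#' nested region masks back to BraTS labels with the precedence
#' ET > TC > WT.  Volumes whose spatial extent is not divisible by the
#' network's downsampling factor are zero-padded and the prediction cropped
#' back.  Optionally applies [postprocess_et()].
#'
#' @param model a `waveseg_model` (or list with `params` and `config`).
#' @param vol a `multimodal_volume`; normalised with [zscore_normalize()]
#'   unless `normalize = FALSE`.
#' @param threshold per-region probability threshold.
#' @param normalize z-score the input first.
#' @param postprocess apply the small-ET relabelling rule.
#' @param et_threshold voxel threshold of the relabelling rule.
#' @return list with `labels` (integer volume), `probabilities`
#'   (`D x H x W x 3`), and `masks` (a `region_mask_set`).
#' @export
predict_volume <- function(model, vol, threshold = 0.5, normalize = TRUE,
                           postprocess = FALSE, et_threshold = 200L) {
  config <- if (inherits(model, "train_config")) model else model$config
  mcfg <- config$model %||% config
  if (normalize) vol <- zscore_normalize(vol)
  x <- vol$channels
  d <- dim(x)[1:3]
  div <- 2^(mcfg$num_levels - 1)
  pad <- (div - d %% div) %% div
  if (any(pad > 0)) {
    xp <- array(0, dim = c(d + pad, 4))
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- xp
  }
  out <- net_forward(model$params, x, mcfg)
  probs <- out$probabilities[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
                             drop = FALSE]
  masks <- structure(list(wt = probs[, , , 1] >= threshold,
                          tc = probs[, , , 2] >= threshold,
                          et = probs[, , , 3] >= threshold),
                     class = "region_mask_set")
  labels <- decode_regions(masks)
  if (postprocess) labels <- postprocess_et(labels, et_threshold)
  list(labels = labels, probabilities = probs, masks = masks)
}

#' Predict and write segmentations for a directory of cases
#'
#' Applies [predict_volume()] to every case directory found under
#' `input_dir` and writes `<case>_seg.nii.gz` files under `out_dir`.
#'
#' @param model a `waveseg_model`.
#' @param input_dir directory containing BraTS-style case sub-directories.
#' @param out_dir output directory.
#' @param ... passed to [predict_volume()].
#' @return character vector of written files, invisibly.
#' @export
predict_cases <- function(model, input_dir, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  case_dirs <- list.dirs(input_dir, recursive = FALSE)
  case_dirs <- case_dirs[vapply(case_dirs, function(cd)
    length(list.files(cd, pattern = "_t1\\.nii(\\.gz)?$")) > 0, logical(1))]
  written <- character(0)
  for (cd in case_dirs) {
    vol <- read_case(cd)
    pred <- predict_volume(model, vol, ...)
    p <- file.path(out_dir, sprintf("%s_seg.nii.gz", vol$case_id))
    RNifti::writeNifti(pred$labels, p, datatype = "int16")
    written <- c(written, p)
  }
  invisible(written)
}
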