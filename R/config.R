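#' Training configuration
#'
#' All hyperparameters of a training run.  Defaults follow the reference
#' protocol: Adam at learning rate 1e-5 with weight decay 1e-4, batch size 1,
#' 100 epochs with polynomial learning-rate decay, random 128^3 crops,
#' mirror-flip probability 0.5 and intensity-shift factor 0.1, and a 4:1
#' case-level train/validation split.
#'
#' @param lr initial learning rate.
#' @param epochs number of passes over the training cases.
#' @param weight_decay L2 weight decay added to the Adam gradients.
#' @param batch_size volumes per optimisation step (1; group statistics in
#'   the network make larger batches unnecessary).
#' @param poly_power exponent of the polynomial decay
#'   `lr_t = lr * (1 - t/T)^power`.
#' @param crop_size random-crop size per axis, or `NULL` to train on full
#'   volumes; must be divisible by `2^(num_levels - 1)`.
#' @param split_ratio train:validation case ratio.
#' @param flip_p per-axis mirror-flip probability.
#' @param shift_factor intensity shift/scale factor.
#' @param augment apply flips and intensity shifts during training.
#' @param normalize apply z-score normalisation when loading cases.
#' @param validate hold out a validation split and track the best checkpoint.
#' @param seed integer seed for initialisation, splitting and augmentation.
#' @param model a [model_config()].
#' @param loss a [loss_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-5, epochs = 100L, weight_decay = 1e-4,
                         batch_size = 1L, poly_power = 0.9,
                         crop_size = c(128L, 128L, 128L),
                         split_ratio = c(4, 1), flip_p = 0.5,
                         shift_factor = 0.1, augment = TRUE,
                         normalize = TRUE, validate = TRUE, seed = 1L,
                         model = model_config(), loss = loss_config()) {
  stopifnot(lr > 0, epochs >= 1, weight_decay >= 0, poly_power > 0)
  div <- 2^(model$num_levels - 1)
  if (!is.null(crop_size) && any(crop_size %% div != 0))
    stop_waveseg("waveseg_config",
                 "crop_size must be divisible by %d", div)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 poly_power = poly_power, crop_size = crop_size,
                 split_ratio = split_ratio, flip_p = flip_p,
                 shift_factor = shift_factor, augment = isTRUE(augment),
                 normalize = isTRUE(normalize), validate = isTRUE(validate),
                 seed = as.integer(seed), model = model, loss = loss),
            class = "train_config")
}

#' Write a configuration to YAML
#' @param config a `train_config` (or any nested list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return a `train_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model <- do.call(model_config, raw$model[intersect(names(raw$model),
                   names(formals(model_config)))])
  loss <- do.call(loss_config, raw$loss[intersect(names(raw$loss),
                  names(formals(loss_config)))])
  args <- raw[intersect(names(raw), setdiff(names(formals(train_config)),
                                            c("model", "loss")))]
  do.call(train_config, c(args, list(model = model, loss = loss)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
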