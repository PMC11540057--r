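#' Z-score normalisation per modality over brain voxels
#'
#' Applies `Z = (m - mu) / sigma` independently per modality, where `mu` and
#' `sigma` are the population mean and standard deviation over that modality's
#' nonzero (brain) voxels.  Background voxels stay exactly zero, the standard
#' treatment for skull-stripped BraTS-style volumes where the air background
#' would otherwise dominate the statistics.
#'
#' @param vol a `multimodal_volume`.
#' @return the normalised `multimodal_volume`; the per-modality statistics are
#'   attached as the `norm_stats` element (list with `mu`, `sigma`).
#' @export
zscore_normalize <- function(vol) {
  stopifnot(inherits(vol, "multimodal_volume"))
  mu <- sigma <- numeric(4)
  for (m in seq_len(4)) {
    ch <- vol$channels[, , , m]
    fg <- ch != 0
    if (!any(fg))
      stop_waveseg("waveseg_degenerate",
                   "modality '%s' has no nonzero voxels", MODALITIES[m])
    v <- ch[fg]
    mu[m] <- mean(v)
    sigma[m] <- sqrt(mean((v - mu[m])^2))   # population sd
    if (sigma[m] == 0)
      stop_waveseg("waveseg_degenerate",
                   "modality '%s' has constant foreground (sigma = 0)",
                   MODALITIES[m])
    ch[fg] <- (v - mu[m]) / sigma[m]
    vol$channels[, , , m] <- ch
  }
  vol$norm_stats <- list(mu = stats::setNames(mu, MODALITIES),
                         sigma = stats::setNames(sigma, MODALITIES))
  vol
}

#' Random crop with one shared offset for channels and labels
#'
#' Crops all four channels and the label volume with a single offset drawn
#' uniformly over all valid positions; deterministic for a fixed seed.
#'
#' @param vol a `multimodal_volume`.
#' @param size integer triple, the crop size per axis.
#' @param seed integer seed.
#' @return the cropped `multimodal_volume`.
#' @export
random_crop <- function(vol, size, seed) {
  stopifnot(inherits(vol, "multimodal_volume"))
  size <- as.integer(size)
  shp <- dim(vol$channels)[1:3]
  if (any(size > shp))
    stop_waveseg("waveseg_invalid_argument",
                 "crop size (%s) exceeds volume shape (%s)",
                 paste(size, collapse = "x"), paste(shp, collapse = "x"))
  off <- with_seed(seed, {
    vapply(seq_len(3), function(a) sample.int(shp[a] - size[a] + 1L, 1L),
           integer(1))
  })
  ix <- lapply(seq_len(3), function(a) off[a]:(off[a] + size[a] - 1L))
  vol$channels <- vol$channels[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  if (!is.null(vol$labels))
    vol$labels <- vol$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  vol$crop_offset <- off
  vol
}

#' Random mirror flips and intensity shift/scale augmentation
#'
#' Each spatial axis is mirrored independently with probability `flip_p`
#' (labels flipped jointly with the channels).  Each modality's foreground
#' (nonzero) intensities are then perturbed as `(v + delta * sd_fg) * s` with
#' `delta ~ U(-shift_factor, shift_factor)` and
#' `s ~ U(1 - shift_factor, 1 + shift_factor)`.  Deterministic per seed.
#'
#' @param vol a `multimodal_volume`.
#' @param flip_p per-axis flip probability in `[0, 1]`.
#' @param shift_factor nonnegative intensity shift/scale factor.
#' @param seed integer seed.
#' @return the augmented `multimodal_volume`.
#' @export
augment_volume <- function(vol, flip_p = 0.5, shift_factor = 0.1, seed = 1L) {
  stopifnot(inherits(vol, "multimodal_volume"),
            flip_p >= 0, flip_p <= 1, shift_factor >= 0)
  with_seed(seed, {
    flips <- runif(3) < flip_p
    for (a in which(flips)) {
      idx <- rev(seq_len(dim(vol$channels)[a]))
      vol$channels <- switch(a,
        vol$channels[idx, , , , drop = FALSE],
        vol$channels[, idx, , , drop = FALSE],
        vol$channels[, , idx, , drop = FALSE])
      if (!is.null(vol$labels))
        vol$labels <- switch(a,
          vol$labels[idx, , , drop = FALSE],
          vol$labels[, idx, , drop = FALSE],
          vol$labels[, , idx, drop = FALSE])
    }
    if (shift_factor > 0) {
      for (m in seq_len(4)) {
        ch <- vol$channels[, , , m]
        fg <- ch != 0
        if (any(fg)) {
          sd_fg <- stats::sd(ch[fg])
          delta <- runif(1, -shift_factor, shift_factor)
          scale <- runif(1, 1 - shift_factor, 1 + shift_factor)
          ch[fg] <- (ch[fg] + delta * sd_fg) * scale
          vol$channels[, , , m] <- ch
        }
      }
    }
    vol$flips <- flips
    vol
  })
}

#' Encode BraTS labels into the nested evaluation regions
#'
#' Maps a label volume with values in \{0, 1, 2, 4\} to the three nested
#' binary evaluation masks: whole tumor `WT = {1, 2, 4}`, tumor core
#' `TC = {1, 4}` and enhancing tumor `ET = {4}`.
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 4\}.
#' @return a `region_mask_set`: list of logical arrays `wt`, `tc`, `et`.
#' @export
encode_regions <- function(labels) {
  check_labels(labels)
  structure(list(wt = array(labels %in% c(1L, 2L, 4L), dim = dim(labels)),
                 tc = array(labels %in% c(1L, 4L), dim = dim(labels)),
                 et = array(labels == 4L, dim = dim(labels))),
            class = "region_mask_set")
}

#' Decode nested region masks back to BraTS labels
#'
#' Inverse of [encode_regions()] with the precedence ET > TC > WT: voxels in
#' `et` become 4, voxels in `tc` only become 1 (necrosis), voxels in `wt` only
#' become 2 (edema).  On mask sets that respect the nesting
#' `et <= tc <= wt` this exactly inverts [encode_regions()].
#'
#' @param masks a `region_mask_set` (or list with `wt`, `tc`, `et`).
#' @return integer label array with values in \{0, 1, 2, 4\}.
#' @export
decode_regions <- function(masks) {
  labels <- array(0L, dim = dim(masks$wt))
  labels[masks$wt] <- 2L
  labels[masks$tc] <- 1L
  labels[masks$et] <- 4L
  labels
}

#' Case-level train/validation split
#'
#' Shuffles the cases deterministically under `seed` and splits them into
#' disjoint, exhaustive train and validation lists with
#' `|train| = round(n * ratio[1] / sum(ratio))`.
#'
#' @param cases character vector (or list) of case identifiers.
#' @param ratio positive length-2 numeric, e.g. `c(4, 1)` for a 4:1 split.
#' @param seed integer seed.
#' @return list with elements `train` and `val`.
#' @export
split_dataset <- function(cases, ratio = c(4, 1), seed = 1L) {
  n <- length(cases)
  if (n < 2)
    stop_waveseg("waveseg_invalid_argument", "need at least 2 cases to split")
  if (length(ratio) != 2 || any(ratio <= 0))
    stop_waveseg("waveseg_invalid_argument", "ratio must be two positive numbers")
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(n * ratio[1] / sum(ratio))
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = cases[sort(perm[seq_len(n_train)])],
       val = cases[sort(perm[(n_train + 1L):n])])
}
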