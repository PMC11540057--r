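#' Specification of a synthetic multimodal phantom
#'
#' Describes a BraTS-like multimodal head phantom: an ellipsoidal "brain" on a
#' zero background containing three nested tumor sub-regions built from
#' axis-aligned ellipsoids with a jittered common centre.  The label
#' convention follows BraTS: 1 = necrotic core (innermost), 4 = enhancing
#' tumor (shell between the necrosis and tumor-core ellipsoids), 2 = edema
#' (shell between the tumor-core and edema ellipsoids), 0 = everything else.
#'
#' @param volume_shape integer triple, voxels per axis; each dimension must be
#'   even and at least 16.
#' @param brain_radius_frac fraction of the half-extent per axis occupied by
#'   the brain ellipsoid.
#' @param region_radii numeric triple of strictly decreasing voxel radii for
#'   the edema, tumor-core and necrosis ellipsoids.
#' @param modality_contrast named list mapping each modality (`t1`, `t1ce`,
#'   `t2`, `flair`) to a numeric vector of mean intensities for the four
#'   tissue classes `c(brain, edema, enhancing, necrosis)`.
#' @param noise_sd standard deviation of the additive Gaussian noise applied
#'   inside the brain mask (intensity units).
#' @param bias_field if `TRUE`, multiply each modality by a smooth
#'   low-frequency multiplicative field (off by default).
#' @param seed integer seed making the phantom reproducible.
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(volume_shape = c(32, 32, 32),
#'                      region_radii = c(8, 5, 2), seed = 1)
#' vol <- generate_phantom(spec)
phantom_spec <- function(volume_shape = c(64, 64, 64),
                         brain_radius_frac = 0.85,
                         region_radii = c(14, 9, 4),
                         modality_contrast = default_contrast(),
                         noise_sd = 4,
                         bias_field = FALSE,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 16) ||
      any(volume_shape %% 2 != 0))
    stop_waveseg("waveseg_invalid_spec",
                 "volume_shape must be three even integers >= 16")
  region_radii <- as.numeric(region_radii)
  if (length(region_radii) != 3 || any(diff(region_radii) >= 0))
    stop_waveseg("waveseg_invalid_spec",
                 "region_radii must be three strictly decreasing radii (edema > core > necrosis)")
  if (region_radii[1] >= brain_radius_frac * min(volume_shape) / 2)
    stop_waveseg("waveseg_invalid_spec",
                 "edema radius %g does not fit inside the brain mask", region_radii[1])
  stopifnot(setequal(names(modality_contrast), MODALITIES))
  structure(list(volume_shape = volume_shape,
                 brain_radius_frac = brain_radius_frac,
                 region_radii = region_radii,
                 modality_contrast = modality_contrast,
                 noise_sd = noise_sd,
                 bias_field = isTRUE(bias_field),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-modality tissue contrasts
#'
#' Mean intensities for `c(brain, edema, enhancing, necrosis)` chosen to mimic
#' the qualitative BraTS appearance: edema bright on T2/FLAIR, the enhancing
#' rim bright on contrast-enhanced T1, necrosis dark on T1/T1ce.
#'
#' @return named list of length-4 numeric vectors.
#' @export
default_contrast <- function() {
  list(t1    = c(brain = 100, edema = 80,  enhancing = 90,  necrosis = 55),
       t1ce  = c(brain = 100, edema = 90,  enhancing = 185, necrosis = 65),
       t2    = c(brain = 100, edema = 165, enhancing = 120, necrosis = 140),
       flair = c(brain = 100, edema = 175, enhancing = 130, necrosis = 110))
}

# Squared normalized ellipsoid coordinate for every voxel of the grid.
ellipsoid_dist2 <- function(shape, center, radii) {
  ax <- (seq_len(shape[1]) - center[1]) / radii[1]
  ay <- (seq_len(shape[2]) - center[2]) / radii[2]
  az <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(ax^2, ay^2, `+`), az^2, `+`)
}

#' Generate a multimodal phantom volume
#'
#' Builds the four modality channels and the shared label volume described by
#' a [phantom_spec()].  Deterministic for a fixed spec seed; the background
#' outside the brain mask is exactly zero in every modality.
#'
#' @param spec a [phantom_spec()].
#' @return a `multimodal_volume`: list with `channels` (array
#'   `D x H x W x 4`, modality order T1, T1ce, T2, FLAIR), `labels` (integer
#'   array with values in \{0, 1, 2, 4\}), `spacing`, and `case_id`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$volume_shape
  with_seed(spec$seed, {
    center <- (shp + 1) / 2
    jitter_max <- pmax(1, 0.05 * shp)
    tumor_center <- center + runif(3, -1, 1) * jitter_max
    brain_radii <- spec$brain_radius_frac * shp / 2
    brain <- ellipsoid_dist2(shp, center, brain_radii) <= 1
    # keep the whole tumor inside the brain: clamp the centre if needed
    margin <- brain_radii - spec$region_radii[1]
    tumor_center <- pmin(pmax(tumor_center, center - 0.5 * margin),
                         center + 0.5 * margin)
    r <- spec$region_radii
    in_edema <- ellipsoid_dist2(shp, tumor_center, rep(r[1], 3)) <= 1
    in_core  <- ellipsoid_dist2(shp, tumor_center, rep(r[2], 3)) <= 1
    in_necro <- ellipsoid_dist2(shp, tumor_center, rep(r[3], 3)) <= 1
    labels <- array(0L, dim = shp)
    labels[in_edema] <- 2L
    labels[in_core]  <- 4L
    labels[in_necro] <- 1L
    labels[!brain] <- 0L

    tissue <- array(1L, dim = shp)           # 1 brain, 2 edema, 3 enh, 4 necro
    tissue[labels == 2L] <- 2L
    tissue[labels == 4L] <- 3L
    tissue[labels == 1L] <- 4L

    channels <- array(0, dim = c(shp, 4))
    dimnames(channels) <- list(NULL, NULL, NULL, MODALITIES)
    bias <- if (spec$bias_field) smooth_bias_field(shp) else NULL
    for (m in seq_along(MODALITIES)) {
      mu <- spec$modality_contrast[[MODALITIES[m]]]
      ch <- array(0, dim = shp)
      ch[brain] <- mu[tissue[brain]]
      if (spec$noise_sd > 0)
        ch[brain] <- ch[brain] + rnorm(sum(brain), sd = spec$noise_sd)
      if (!is.null(bias)) ch[brain] <- ch[brain] * bias[brain]
      channels[, , , m] <- ch
    }
    out <- multimodal_volume(channels, labels,
                             case_id = sprintf("phantom_%06d", spec$seed))
    out$tumor_center <- tumor_center   # geometry kept for exact auditing
    out
  })
}

# Smooth multiplicative field around 1, built from a few low-frequency cosines.
smooth_bias_field <- function(shape) {
  ax <- cos(pi * seq(0, 1, length.out = shape[1]) * runif(1, 0.5, 1.5))
  ay <- cos(pi * seq(0, 1, length.out = shape[2]) * runif(1, 0.5, 1.5))
  az <- cos(pi * seq(0, 1, length.out = shape[3]) * runif(1, 0.5, 1.5))
  f <- outer(outer(ax, ay, `+`), az, `+`) / 3
  1 + 0.15 * f
}

#' Construct a multimodal volume container
#'
#' @param channels array `D x H x W x 4` holding the T1, T1ce, T2 and FLAIR
#'   channels in that fixed order.
#' @param labels optional integer array of the same spatial shape with values
#'   in \{0, 1, 2, 4\}.
#' @param spacing voxel spacing in mm (length 3).
#' @param case_id identifier string.
#' @return object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(channels, labels = NULL,
                              spacing = c(1, 1, 1), case_id = "case") {
  stopifnot(length(dim(channels)) == 4, dim(channels)[4] == 4)
  if (!is.null(labels)) {
    stopifnot(all(dim(labels) == dim(channels)[1:3]))
    check_labels(labels)
    storage.mode(labels) <- "integer"
  }
  structure(list(channels = channels, labels = labels,
                 spacing = as.numeric(spacing), case_id = case_id),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<multimodal_volume> %s  %dx%dx%d, 4 modalities, labels: %s\n",
              x$case_id, d[1], d[2], d[3],
              if (is.null(x$labels)) "none"
              else paste(sort(unique(as.integer(x$labels))), collapse = ",")))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom cases in BraTS layout: one directory per case holding
#' `<case>_{t1,t1ce,t2,flair,seg}.nii.gz`, plus a JSON manifest listing paths
#' and per-case seeds (`seed_i = spec$seed + i - 1`).
#'
#' @param n number of cases (>= 1).
#' @param spec a [phantom_spec()] used as the template; only the seed varies
#'   between cases.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly a list with `cases` and `manifest_path`.
#' @export
generate_dataset <- function(n, spec, out_dir) {
  stopifnot(n >= 1, inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_waveseg("waveseg_io", "cannot create output directory '%s'", out_dir)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    vol <- generate_phantom(sp)
    case_id <- sprintf("case_%04d", i)
    vol$case_id <- case_id
    case_dir <- file.path(out_dir, case_id)
    write_case(vol, case_dir)
    cases[[i]] <- list(case_id = case_id, dir = case_dir, seed = sp$seed)
  }
  manifest <- list(n = n, out_dir = out_dir, base_seed = spec$seed,
                   volume_shape = spec$volume_shape, cases = cases)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(cases = cases, manifest_path = manifest_path))
}
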