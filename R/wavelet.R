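#' Orthonormal wavelet filter pairs
#'
#' Returns the analysis lowpass/highpass filter pair for the requested
#' wavelet.  `haar`/`db1` is the default family used inside the network: it is
#' orthonormal, exact on even extents, and the cheapest choice inside a
#' training loop.  `db2` is provided as a longer orthonormal alternative.
#'
#' @param name wavelet identifier: `"haar"`, `"db1"` or `"db2"`.
#' @return list with `lo` and `hi` numeric filters.
#' @export
wavelet_filters <- function(name = "haar") {
  switch(tolower(name),
    haar = , db1 = {
      list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2))
    },
    db2 = {
      s3 <- sqrt(3)
      lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
      hi <- rev(lo) * c(1, -1, 1, -1)   # quadrature mirror
      list(lo = lo, hi = hi)
    },
    stop_waveseg("waveseg_config", "unknown wavelet '%s'", name))
}

# L x L periodized analysis matrix: first L/2 rows lowpass, last L/2 highpass.
# Orthogonal whenever L is even and L >= filter length.
dwt_matrix <- function(L, filt) {
  if (L %% 2 != 0)
    stop_waveseg("waveseg_invalid_argument", "axis extent %d is odd", L)
  if (L < length(filt$lo))
    stop_waveseg("waveseg_invalid_argument",
                 "axis extent %d shorter than the wavelet filter", L)
  W <- matrix(0, L, L)
  h <- L / 2
  for (k in seq_len(h)) {
    cols <- ((2 * (k - 1) + seq_along(filt$lo) - 1) %% L) + 1
    for (m in seq_along(filt$lo)) {
      W[k, cols[m]] <- W[k, cols[m]] + filt$lo[m]
      W[h + k, cols[m]] <- W[h + k, cols[m]] + filt$hi[m]
    }
  }
  W
}

# Apply matrix W along one axis of a 3D array.
apply_axis <- function(x, W, axis) {
  d <- dim(x)
  if (axis == 1) {
    y <- W %*% matrix(x, d[1])
    dim(y) <- d
    y
  } else {
    perm <- if (axis == 2) c(2, 1, 3) else c(3, 2, 1)
    xp <- aperm(x, perm)
    dp <- dim(xp)
    y <- W %*% matrix(xp, dp[1])
    dim(y) <- dp
    aperm(y, perm)
  }
}

# Symmetric one-slice padding to make every axis even; records original shape.
pad_to_even <- function(x) {
  d <- dim(x)
  for (a in which(d %% 2 != 0)) {
    n <- dim(x)[a]
    idx <- c(seq_len(n), n)   # replicate the boundary slice
    x <- switch(a,
      x[idx, , , drop = FALSE],
      x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE])
  }
  x
}

#' Single-level separable 3D discrete wavelet transform
#'
#' Decomposes a 3D volume into eight subbands (one low-frequency `lll` plus
#' seven high-frequency bands) with a single-level separable transform,
#' implemented as a 2D transform of every z-slice followed by a 1D transform
#' along z.  Boundary handling is periodization for even extents (no
#' coefficient growth); odd extents are symmetric-padded by one slice, with
#' the original shape recorded for exact inversion.  For orthonormal filters
#' the transform conserves energy on even extents.
#'
#' @param volume numeric 3D array.
#' @param wavelet wavelet identifier, see [wavelet_filters()].
#' @return a `subband_set`: list of the eight subband arrays (`lll`, `hll`,
#'   `lhl`, `hhl`, `llh`, `hlh`, `lhh`, `hhh`; the first letter is the x-axis
#'   filter, then y, then z), plus `wavelet_name` and `original_shape`.
#' @export
dwt3 <- function(volume, wavelet = "haar") {
  if (length(volume) == 0 || length(dim(volume)) != 3)
    stop_waveseg("waveseg_invalid_argument", "volume must be a nonempty 3D array")
  filt <- wavelet_filters(wavelet)
  orig <- dim(volume)
  x <- pad_to_even(volume)
  d <- dim(x)
  Wx <- dwt_matrix(d[1], filt); Wy <- dwt_matrix(d[2], filt)
  Wz <- dwt_matrix(d[3], filt)
  # 2D transform per z-slice, then 1D along z (separable, so the slice loop
  # collapses to whole-array axis applications)
  y <- apply_axis(apply_axis(x, Wx, 1), Wy, 2)
  y <- apply_axis(y, Wz, 3)
  h <- d %/% 2
  lo <- lapply(seq_len(3), function(a) seq_len(h[a]))
  hi <- lapply(seq_len(3), function(a) (h[a] + 1):d[a])
  band <- function(ix, iy, iz) y[ix, iy, iz, drop = FALSE]
  structure(list(
    lll = band(lo[[1]], lo[[2]], lo[[3]]),
    hll = band(hi[[1]], lo[[2]], lo[[3]]),
    lhl = band(lo[[1]], hi[[2]], lo[[3]]),
    hhl = band(hi[[1]], hi[[2]], lo[[3]]),
    llh = band(lo[[1]], lo[[2]], hi[[3]]),
    hlh = band(hi[[1]], lo[[2]], hi[[3]]),
    lhh = band(lo[[1]], hi[[2]], hi[[3]]),
    hhh = band(hi[[1]], hi[[2]], hi[[3]]),
    wavelet_name = wavelet,
    original_shape = orig), class = "subband_set")
}

SUBBAND_NAMES <- c("lll", "hll", "lhl", "hhl", "llh", "hlh", "lhh", "hhh")

#' Single-level inverse 3D discrete wavelet transform
#'
#' Exact inverse of [dwt3()]: reassembles the eight subbands and applies the
#' transposed (orthogonal) analysis matrices, cropping back to the recorded
#' original shape when the input had odd extents.
#'
#' @param subbands a `subband_set` from [dwt3()].
#' @return numeric 3D array of shape `original_shape`.
#' @export
idwt3 <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  shp <- dim(subbands$lll)
  for (nm in SUBBAND_NAMES)
    if (!all(dim(subbands[[nm]]) == shp))
      stop_waveseg("waveseg_invalid_argument",
                   "subband '%s' has mismatched shape", nm)
  filt <- wavelet_filters(subbands$wavelet_name)
  d <- 2L * shp
  y <- array(0, dim = d)
  h <- shp
  lo <- lapply(seq_len(3), function(a) seq_len(h[a]))
  hi <- lapply(seq_len(3), function(a) (h[a] + 1):d[a])
  y[lo[[1]], lo[[2]], lo[[3]]] <- subbands$lll
  y[hi[[1]], lo[[2]], lo[[3]]] <- subbands$hll
  y[lo[[1]], hi[[2]], lo[[3]]] <- subbands$lhl
  y[hi[[1]], hi[[2]], lo[[3]]] <- subbands$hhl
  y[lo[[1]], lo[[2]], hi[[3]]] <- subbands$llh
  y[hi[[1]], lo[[2]], hi[[3]]] <- subbands$hlh
  y[lo[[1]], hi[[2]], hi[[3]]] <- subbands$lhh
  y[hi[[1]], hi[[2]], hi[[3]]] <- subbands$hhh
  Wx <- dwt_matrix(d[1], filt); Wy <- dwt_matrix(d[2], filt)
  Wz <- dwt_matrix(d[3], filt)
  x <- apply_axis(y, t(Wz), 3)
  x <- apply_axis(x, t(Wy), 2)
  x <- apply_axis(x, t(Wx), 1)
  orig <- subbands$original_shape
  x[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), drop = FALSE]
}

#' Channel-wise 3D DWT of a feature stack
#'
#' Applies [dwt3()] independently to every channel of a `D x H x W x C`
#' array; there is no cross-channel mixing.
#'
#' @param stack numeric 4D array (`D x H x W x C`).
#' @param wavelet wavelet identifier.
#' @return list of `C` `subband_set`s.
#' @export
batched_dwt3 <- function(stack, wavelet = "haar") {
  stopifnot(length(dim(stack)) == 4)
  lapply(seq_len(dim(stack)[4]), function(c)
    dwt3(array(stack[, , , c], dim = dim(stack)[1:3]), wavelet))
}

#' Channel-wise inverse 3D DWT
#'
#' @param subband_list list of `subband_set`s, one per channel.
#' @return numeric 4D array (`D x H x W x C`).
#' @export
batched_idwt3 <- function(subband_list) {
  chans <- lapply(subband_list, idwt3)
  array(unlist(chans, use.names = FALSE),
        dim = c(dim(chans[[1]]), length(chans)))
}
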