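# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's implementation paths (matrix transforms, distance
# transforms) so agreement is evidence, not tautology.

# Periodized 1D analysis step by explicit filter convolution.
dwt1d_oracle <- function(x, lo, hi) {
  L <- length(x)
  h <- L / 2
  a <- d <- numeric(h)
  for (k in seq_len(h)) {
    for (m in seq_along(lo)) {
      idx <- ((2 * (k - 1) + m - 1) %% L) + 1
      a[k] <- a[k] + lo[m] * x[idx]
      d[k] <- d[k] + hi[m] * x[idx]
    }
  }
  c(a, d)
}

# Axis-sequential 3D DWT: 1D transform along x, then y, then z, via loops.
dwt3_oracle <- function(vol, wavelet = "haar") {
  f <- waveseg::wavelet_filters(wavelet)
  d <- dim(vol)
  y <- vol
  for (z in seq_len(d[3])) for (yy in seq_len(d[2]))
    y[, yy, z] <- dwt1d_oracle(y[, yy, z], f$lo, f$hi)
  for (z in seq_len(d[3])) for (xx in seq_len(d[1]))
    y[xx, , z] <- dwt1d_oracle(y[xx, , z], f$lo, f$hi)
  for (yy in seq_len(d[2])) for (xx in seq_len(d[1]))
    y[xx, yy, ] <- dwt1d_oracle(y[xx, yy, ], f$lo, f$hi)
  h <- d %/% 2
  lo <- lapply(1:3, function(a) seq_len(h[a]))
  hi <- lapply(1:3, function(a) (h[a] + 1):d[a])
  list(lll = y[lo[[1]], lo[[2]], lo[[3]], drop = FALSE],
       hll = y[hi[[1]], lo[[2]], lo[[3]], drop = FALSE],
       lhl = y[lo[[1]], hi[[2]], lo[[3]], drop = FALSE],
       hhl = y[hi[[1]], hi[[2]], lo[[3]], drop = FALSE],
       llh = y[lo[[1]], lo[[2]], hi[[3]], drop = FALSE],
       hlh = y[hi[[1]], lo[[2]], hi[[3]], drop = FALSE],
       lhh = y[lo[[1]], hi[[2]], hi[[3]], drop = FALSE],
       hhh = y[hi[[1]], hi[[2]], hi[[3]], drop = FALSE])
}

# All-pairs percentile Hausdorff oracle on surface voxel coordinates.
hd95_oracle <- function(pred, truth, spacing = c(1, 1, 1), percentile = 95) {
  sp <- which(waveseg::surface_voxels(pred), arr.ind = TRUE)
  sq <- which(waveseg::surface_voxels(truth), arr.ind = TRUE)
  sp <- sweep(sp, 2, spacing, `*`)
  sq <- sweep(sq, 2, spacing, `*`)
  dmat <- outer(rowSums(sp^2), rowSums(sq^2), `+`) - 2 * sp %*% t(sq)
  dmat[dmat < 0] <- 0
  dmat <- sqrt(dmat)
  d_pq <- apply(dmat, 1, min)
  d_qp <- apply(dmat, 2, min)
  max(quantile(d_pq, percentile / 100, names = FALSE),
      quantile(d_qp, percentile / 100, names = FALSE))
}

# Naive position-loop version of the global-context block.
gcam_oracle <- function(s, p) {
  d <- dim(s)
  N <- prod(d[1:3]); C <- d[4]
  S <- matrix(s, N, C)
  logits <- numeric(N)
  for (n in seq_len(N)) logits[n] <- sum(S[n, ] * p$key_w) + p$key_b
  w <- exp(logits - max(logits)); w <- w / sum(w)
  ctx <- numeric(C)
  for (n in seq_len(N)) ctx <- ctx + w[n] * S[n, ]
  h <- as.numeric(ctx %*% p$w1) + p$b1
  mu <- mean(h); va <- mean((h - mu)^2)
  h <- p$ln_gamma * (h - mu) / sqrt(va + 1e-5) + p$ln_beta
  h <- pmax(h, 0)
  tr <- as.numeric(h %*% p$w2) + p$b2
  out <- S
  for (n in seq_len(N)) out[n, ] <- S[n, ] + tr
  array(out, dim = d)
}

# Small random blob mask: a couple of spheres on a grid.
random_blob <- function(shape, n_spheres = 2, r_range = c(2, 4), seed = 1) {
  withr::with_seed(seed, {
    m <- array(FALSE, dim = shape)
    ax <- lapply(shape, seq_len)
    for (i in seq_len(n_spheres)) {
      ce <- sapply(shape, function(s) runif(1, 4, s - 3))
      r <- runif(1, r_range[1], r_range[2])
      d2 <- outer(outer((ax[[1]] - ce[1])^2, (ax[[2]] - ce[2])^2, `+`),
                  (ax[[3]] - ce[3])^2, `+`)
      m <- m | (d2 <= r^2)
    }
    m
  })
}

tiny_phantom_spec <- function(seed = 1L, noise_sd = 0, shape = c(32, 32, 32),
                              radii = c(8, 5, 2)) {
  waveseg::phantom_spec(volume_shape = shape, region_radii = radii,
                        noise_sd = noise_sd, seed = seed)
}
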