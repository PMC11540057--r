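# Differentiable layers used by the segmentation network.  Forward values are
# plain R arrays of dim (D, H, W, C); convolution is im2col + GEMM through the
# compiled kernels, so the heavy lifting runs in BLAS.

ad_add <- function(a, b) {
  ad_op(ad_value(a) + ad_value(b), list(a, b),
        function(g) list(g, g))
}

ad_relu <- function(x) {
  v <- ad_value(x)
  mask <- v > 0
  ad_op(v * mask, list(x), function(g) list(g * mask))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ad_value(x)))
  ad_op(v, list(x), function(g) list(g * v * (1 - v)))
}

# 3D convolution, kernel k x k x k, zero padding `pad`, isotropic stride.
# w: array (k, k, k, C_in, C_out); b: length C_out.
ad_conv3d <- function(x, w, b, stride = 1L, pad = NULL) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  k <- dim(wv)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  dims <- dim(xv)
  cin <- dim(wv)[4]; cout <- dim(wv)[5]
  stopifnot(dims[4] == cin)
  wmat <- matrix(wv, k^3 * cin, cout)
  cols <- cpp_im2col(xv, dims, k, stride, pad)
  out <- cols %*% wmat
  out <- sweep(out, 2, bv, `+`)
  odim <- c((dims[1:3] + 2 * pad - k) %/% stride + 1L, cout)
  dim(out) <- odim
  cols <- NULL                                # big; rebuilt in the backward
  need_dx <- inherits(x, "ad_node") &&
    (x$requires_grad || length(x$parents) > 0)
  ad_op(out, list(x, w, b), function(g) {
    gmat <- matrix(g, prod(odim[1:3]), cout)
    cols <- cpp_im2col(xv, dims, k, stride, pad)
    dw <- crossprod(cols, gmat)
    dim(dw) <- dim(wv)
    dx <- if (need_dx)
      cpp_col2im(tcrossprod(gmat, wmat), dims, k, stride, pad)
    list(dx, dw, colSums(gmat))
  })
}

# Group normalisation over (spatial x channels-in-group); gamma/beta per channel.
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- ad_value(x); gv <- ad_value(gamma); bv <- ad_value(beta)
  d <- dim(xv)
  N <- prod(d[1:3]); C <- d[4]
  if (C %% groups != 0) groups <- 1L
  cg <- C %/% groups
  xm <- matrix(xv, N, C)
  xhat <- matrix(0, N, C)
  mu <- va <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    xg <- xm[, cols]
    mu[g] <- mean(xg)
    va[g] <- mean((xg - mu[g])^2)
    xhat[, cols] <- (xg - mu[g]) / sqrt(va[g] + eps)
  }
  out <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
  dim(out) <- d
  ad_op(out, list(x, gamma, beta), function(gr) {
    grm <- matrix(gr, N, C)
    dgamma <- colSums(grm * xhat)
    dbeta <- colSums(grm)
    dx <- matrix(0, N, C)
    for (g in seq_len(groups)) {
      cols <- ((g - 1) * cg + 1):(g * cg)
      istd <- 1 / sqrt(va[g] + eps)
      dxh <- sweep(grm[, cols, drop = FALSE], 2, gv[cols], `*`)
      xh <- xhat[, cols, drop = FALSE]
      m1 <- mean(dxh)
      m2 <- mean(dxh * xh)
      dx[, cols] <- istd * (dxh - m1 - xh * m2)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

ad_upsample2 <- function(x) {
  xv <- ad_value(x)
  dims <- dim(xv)
  out <- cpp_upsample2(xv, dims)
  ad_op(out, list(x), function(g) list(cpp_upsample2_adj(g, dims)))
}

# Concatenate along the channel axis.
ad_concat <- function(xs) {
  vals <- lapply(xs, ad_value)
  d <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[4], numeric(1))
  out <- array(unlist(vals, use.names = FALSE), dim = c(d[1:3], sum(chans)))
  ends <- cumsum(chans)
  starts <- ends - chans + 1
  ad_op(out, xs, function(g) {
    lapply(seq_along(xs), function(i)
      g[, , , starts[i]:ends[i], drop = FALSE])
  })
}

# Wavelet fusion of four modality maps: mean of the low subband, sum (or
# mean) of the high subbands, channel-wise.  The map is linear; for
# orthonormal wavelets on even extents it is self-adjoint up to the diagonal
# subband scaling, so the backward pass reuses the forward operator.  Odd
# extents (replicate-padded inside dwt3) need the exact adjoint: zero-pad the
# gradient, apply the even-extent core, then fold the padded slice back.
ad_wfuse <- function(xs, wavelet = "haar", high_freq_rule = "sum") {
  if (!high_freq_rule %in% c("sum", "mean"))
    stop_waveseg("waveseg_config",
                 "trainable fusion supports high_freq_rule 'sum' or 'mean' only")
  vals <- lapply(xs, ad_value)
  d <- dim(vals[[1]])
  hscale <- if (high_freq_rule == "sum") 1 else 1 / 4
  filt <- wavelet_filters(wavelet)
  # batched core: transform all channels at once; the low-frequency subband
  # is the contiguous (1:h1, 1:h2, 1:h3) block of the transformed stack, so
  # the fusion scaling never needs to unpack subbands.
  axis4 <- function(x, W, axis) {
    dd <- dim(x)
    if (axis == 1) {
      y <- W %*% matrix(x, dd[1]); dim(y) <- dd; y
    } else {
      perm <- if (axis == 2) c(2, 1, 3, 4) else c(3, 2, 1, 4)
      xp <- aperm(x, perm)
      dp <- dim(xp)
      y <- W %*% matrix(xp, dp[1]); dim(y) <- dp
      aperm(y, perm)
    }
  }
  apply_A <- function(v) {
    dd <- dim(v)
    even <- dd[1:3] %% 2 == 0
    if (!all(even)) {                        # rare: replicate-pad odd axes
      for (a in which(!even)) {
        n <- dd[a]
        idx <- c(seq_len(n), n)
        v <- switch(a, v[idx, , , , drop = FALSE], v[, idx, , , drop = FALSE],
                    v[, , idx, , drop = FALSE])
      }
    }
    de <- dim(v)[1:3]
    Ws <- lapply(de, dwt_matrix, filt = filt)
    y <- axis4(axis4(axis4(v, Ws[[1]], 1), Ws[[2]], 2), Ws[[3]], 3)
    h <- de %/% 2
    if (hscale != 1) y <- y * hscale
    y[1:h[1], 1:h[2], 1:h[3], ] <- y[1:h[1], 1:h[2], 1:h[3], , drop = FALSE] *
      (0.25 / hscale)
    y <- axis4(axis4(axis4(y, t(Ws[[3]]), 3), t(Ws[[2]]), 2), t(Ws[[1]]), 1)
    y[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]), , drop = FALSE]
  }
  f <- apply_A(vals[[1]] + vals[[2]] + vals[[3]] + vals[[4]])
  odd <- d[1:3] %% 2 == 1
  ad_op(f, xs, function(g) {
    gi <- if (!any(odd)) apply_A(g) else {
      de <- d[1:3] + odd                       # even padded extents
      gz <- array(0, dim = c(de, d[4]))
      gz[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- g
      full <- apply_A(gz)
      for (a in which(odd)) {                  # adjoint of replicate padding
        n <- d[a]
        fold <- function(x, sl) switch(a,
          x[sl, , , , drop = FALSE], x[, sl, , , drop = FALSE],
          x[, , sl, , drop = FALSE])
        last <- fold(full, n) + fold(full, n + 1)
        full <- fold(full, seq_len(n))
        switch(a, full[n, , , ] <- last, full[, n, , ] <- last,
               full[, , n, ] <- last)
      }
      full
    }
    list(gi, gi, gi, gi)
  })
}

# Global-context attention block as one fused op with a hand-derived backward.
# Parameter order: key_w, key_b, w1, b1, ln_gamma, ln_beta, w2, b2.
ad_gcam <- function(x, key_w, key_b, w1, b1, ln_gamma, ln_beta, w2, b2,
                    eps = 1e-5) {
  xv <- ad_value(x)
  d <- dim(xv)
  N <- prod(d[1:3]); C <- d[4]
  S <- matrix(xv, N, C)
  kw <- matrix(ad_value(key_w), C, 1)
  z <- as.numeric(S %*% kw) + ad_value(key_b)
  w <- exp(z - max(z)); w <- w / sum(w)
  ctx <- as.numeric(crossprod(S, w))
  w1v <- ad_value(w1); w2v <- ad_value(w2)
  g1 <- ad_value(ln_gamma); b1v <- ad_value(b1)
  h0 <- as.numeric(ctx %*% w1v) + b1v
  mu <- mean(h0); va <- mean((h0 - mu)^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- (h0 - mu) * istd
  h1 <- g1 * xhat + ad_value(ln_beta)
  relu_mask <- h1 > 0
  h2 <- h1 * relu_mask
  tvec <- as.numeric(h2 %*% w2v) + ad_value(b2)
  out <- sweep(xv, 4, tvec, `+`)
  ad_op(out, list(x, key_w, key_b, w1, b1, ln_gamma, ln_beta, w2, b2),
        function(g) {
    gm <- matrix(g, N, C)
    dS <- gm                              # identity path of the fusion
    dt <- colSums(gm)
    dw2 <- outer(h2, dt)
    db2 <- dt
    dh2 <- as.numeric(w2v %*% dt)
    dh1 <- dh2 * relu_mask
    dgamma <- dh1 * xhat
    dbeta <- dh1
    dxhat <- dh1 * g1
    dh0 <- istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    dctx <- as.numeric(w1v %*% dh0)
    dw1 <- outer(ctx, dh0)
    db1 <- dh0
    # context pooling: ctx = S' w, w = softmax(S kw + kb)
    dS <- dS + outer(w, dctx)
    dwgt <- as.numeric(S %*% dctx)
    dz <- w * (dwgt - sum(w * dwgt))
    dS <- dS + outer(dz, as.numeric(kw))
    dkw <- crossprod(S, dz)
    dkb <- sum(dz)
    dim(dS) <- d
    list(dS, dkw, dkb, dw1, db1, dgamma, dbeta, dw2, db2)
  })
}

# Combined BCE + soft-Dice loss on sigmoid probabilities, mean over voxels
# and the three region channels.  Returns a scalar node; `parts` attribute
# carries the two components.
ad_bce_dice_loss <- function(pred, target, epsilon = 1e-5, clip = 1e-7) {
  pv <- ad_value(pred)
  d <- dim(pv)
  R <- d[4]
  u <- target
  v <- pmin(pmax(pv, clip), 1 - clip)
  ntot <- length(v)
  bce <- -mean(u * log(v) + (1 - u) * log(1 - v))
  um <- matrix(u, ncol = R); vm <- matrix(v, ncol = R)
  inter <- colSums(um * vm)
  su <- colSums(um); sv <- colSums(vm)
  dice_r <- 1 - (2 * inter + epsilon) / (su + sv + epsilon)
  dice <- mean(dice_r)
  node <- ad_op(bce + dice, list(pred), function(g) {
    dbce <- -(u / v - (1 - u) / (1 - v)) / ntot
    # d(dice_r)/dv_i = A_r / B_r^2 - 2 u_i / B_r, channel mean adds 1/R
    A <- 2 * inter + epsilon
    B <- su + sv + epsilon
    ddice <- sweep(-2 * um, 2, B, `/`) +
             matrix(A / B^2, nrow = nrow(um), ncol = R, byrow = TRUE)
    dv <- array((as.numeric(dbce) + as.numeric(ddice) / R) * g, dim = d)
    list(dv)
  })
  attr(node, "parts") <- c(bce = bce, dice = dice)
  node
}

# Same objective taken on the logits.  The BCE gradient is computed in logit
# space, (v - u)/N, which stays informative when the sigmoid saturates --
# with the probability-space form a head that collapses early to "all
# background" sits in a vanishing-gradient regime and can never recover.
ad_bce_dice_loss_logits <- function(logits, target, epsilon = 1e-5,
                                    clip = 1e-7) {
  z <- ad_value(logits)
  d <- dim(z)
  R <- d[4]
  u <- target
  v <- 1 / (1 + exp(-z))
  vc <- pmin(pmax(v, clip), 1 - clip)
  ntot <- length(v)
  bce <- -mean(u * log(vc) + (1 - u) * log(1 - vc))
  um <- matrix(u, ncol = R); vm <- matrix(v, ncol = R)
  inter <- colSums(um * vm)
  su <- colSums(um); sv <- colSums(vm)
  dice_r <- 1 - (2 * inter + epsilon) / (su + sv + epsilon)
  dice <- mean(dice_r)
  node <- ad_op(bce + dice, list(logits), function(g) {
    dbce <- (v - u) / ntot
    A <- 2 * inter + epsilon
    B <- su + sv + epsilon
    ddice <- sweep(-2 * um, 2, B, `/`) +
             matrix(A / B^2, nrow = nrow(um), ncol = R, byrow = TRUE)
    dz <- array((as.numeric(dbce) +
                 as.numeric(ddice) / R * as.numeric(v * (1 - v))) * g, dim = d)
    list(dz)
  })
  attr(node, "parts") <- c(bce = bce, dice = dice)
  node
}
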