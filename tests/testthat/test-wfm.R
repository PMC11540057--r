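rand_stack <- function(C = 3, d = c(8, 8, 8), seed = 1) {
  withr::with_seed(seed, lapply(1:4, function(i)
    array(rnorm(prod(d) * C), dim = c(d, C))))
}

test_that("subband fusion averages lows and sums highs", {
  withr::with_seed(11, {
    x <- array(rnorm(8^3), dim = c(8, 8, 8))
    sb <- dwt3(x)
    for (nm in waveseg:::SUBBAND_NAMES[-1]) sb[[nm]] <- sb[[nm]] * 0
    fused <- fuse_subbands(list(sb, sb, sb, sb))
    expect_equal(fused$lll, sb$lll, tolerance = 1e-12)   # mean of identical
    expect_true(all(fused$hhh == 0))                     # sum of zeros
    # cancellation under summation
    sets <- lapply(1:4, function(i) dwt3(array(rnorm(8^3), dim = c(8, 8, 8))))
    e <- sets[[1]]$hll
    sets[[2]]$hll <- -e; sets[[1]]$hll <- e
    sets[[3]]$hll <- e * 0; sets[[4]]$hll <- e * 0
    expect_true(all(fuse_subbands(sets)$hll == 0))
    # independent mean/sum recomputation, exact
    f <- fuse_subbands(sets)
    expect_identical(f$lll, (sets[[1]]$lll + sets[[2]]$lll + sets[[3]]$lll +
                             sets[[4]]$lll) / 4)
    expect_identical(f$lhh, sets[[1]]$lhh + sets[[2]]$lhh + sets[[3]]$lhh +
                            sets[[4]]$lhh)
    expect_error(fuse_subbands(sets[1:3]), class = "waveseg_invalid_argument")
  })
})

test_that("wavelet fusion of identical constant maps is the identity", {
  ones <- lapply(1:4, function(i) array(1, dim = c(8, 8, 8, 2)))
  expect_equal(wavelet_fuse(ones), ones[[1]], tolerance = 1e-10)
})

test_that("fusing one live modality attenuates lows and preserves highs", {
  withr::with_seed(12, {
    x <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 2))
    zero <- array(0, dim = dim(x))
    f <- wavelet_fuse(list(x, zero, zero, zero))
    # closed form by linearity: IDWT(lll/4, highs unchanged), channel-wise
    expected <- vapply(1:2, function(ch) {
      sb <- dwt3(x[, , , ch])
      sb$lll <- sb$lll / 4
      idwt3(sb)
    }, array(0, dim = c(8, 8, 8)))
    expect_equal(f, array(expected, dim = dim(x)), tolerance = 1e-10)
  })
})

test_that("wavelet fusion is symmetric in the modalities and homogeneous", {
  st <- rand_stack(seed = 13)
  f <- wavelet_fuse(st)
  expect_equal(wavelet_fuse(st[c(4, 2, 1, 3)]), f, tolerance = 1e-10)
  expect_equal(wavelet_fuse(lapply(st, `*`, 2.5)), 2.5 * f, tolerance = 1e-10)
})

test_that("module forward adds the fused map and concatenates in modality order", {
  ones <- lapply(1:4, function(i) array(1, dim = c(8, 8, 8, 2)))
  out1 <- wfm_forward(ones)
  expect_equal(dim(out1), c(8, 8, 8, 8))
  expect_equal(as.numeric(out1), rep(2, length(out1)), tolerance = 1e-10)
  zeros <- lapply(1:4, function(i) array(0, dim = c(8, 8, 8, 2)))
  expect_true(all(wfm_forward(zeros) == 0))
  st <- rand_stack(C = 3, seed = 14)
  out <- wfm_forward(st)
  expect_equal(dim(out), c(8, 8, 8, 12))
  f <- wavelet_fuse(st)
  expect_equal(out[, , , 1:3], st[[1]] + f, tolerance = 1e-12)
  expect_equal(out[, , , 10:12], st[[4]] + f, tolerance = 1e-12)
  # deterministic, parameter-free
  expect_identical(wfm_forward(st), out)
})

test_that("shape mismatches in the feature stack are rejected", {
  st <- rand_stack(seed = 15)
  st[[3]] <- st[[3]][, , 1:4, , drop = FALSE]
  expect_error(wfm_forward(st), class = "waveseg_invalid_argument")
  expect_error(wfm_forward(st[1:2]), class = "waveseg_invalid_argument")
})
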