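test_that("high-pass subbands annihilate constant volumes", {
  for (val in c(1, -3.7)) {
    sb <- dwt3(array(val, dim = c(8, 8, 8)))
    for (nm in c("hll", "lhl", "hhl", "llh", "hlh", "lhh", "hhh"))
      expect_lt(max(abs(sb[[nm]])), 1e-9)
  }
})

test_that("orthonormal Haar on a 2x2x2 block of ones gives LLL = 2*sqrt(2)", {
  sb <- dwt3(array(1, dim = c(2, 2, 2)), "haar")
  expect_equal(as.numeric(sb$lll), 2 * sqrt(2), tolerance = 1e-12)
  expect_lt(max(abs(unlist(sb[2:8]))), 1e-12)
})

test_that("slice-wise transform matches the axis-sequential filter-loop oracle", {
  withr::with_seed(7, {
    for (wav in c("haar", "db2")) {
      x <- array(rnorm(16^3), dim = c(16, 16, 16))
      sb <- dwt3(x, wav)
      oracle <- dwt3_oracle(x, wav)
      for (nm in names(oracle))
        expect_lt(max(abs(sb[[nm]] - oracle[[nm]])), 1e-6)
    }
  })
})

test_that("analysis followed by synthesis reconstructs the input", {
  withr::with_seed(8, {
    x <- array(rnorm(16^3), dim = c(16, 16, 16))
    expect_lt(max(abs(idwt3(dwt3(x)) - x)), 1e-5)
    expect_lt(max(abs(idwt3(dwt3(x, "db2")) - x)), 1e-5)
    # odd extents via symmetric padding bookkeeping
    xo <- array(rnorm(5 * 6 * 7), dim = c(5, 6, 7))
    expect_lt(max(abs(idwt3(dwt3(xo)) - xo)), 1e-10)
    # zero subbands reconstruct zero; LLL-only keeps a constant volume
    sb0 <- dwt3(array(0, dim = c(4, 4, 4)))
    expect_true(all(idwt3(sb0) == 0))
    sbc <- dwt3(array(2.5, dim = c(8, 8, 8)))
    for (nm in c("hll", "lhl", "hhl", "llh", "hlh", "lhh", "hhh"))
      sbc[[nm]] <- sbc[[nm]] * 0
    expect_equal(idwt3(sbc), array(2.5, dim = c(8, 8, 8)), tolerance = 1e-10)
  })
})

test_that("orthonormal transforms conserve energy and are linear", {
  withr::with_seed(9, {
    x <- array(rnorm(8^3), dim = c(8, 8, 8))
    y <- array(rnorm(8^3), dim = c(8, 8, 8))
    sb <- dwt3(x)
    e_sub <- sum(vapply(waveseg:::SUBBAND_NAMES, function(n) sum(sb[[n]]^2),
                        numeric(1)))
    expect_lt(abs(sum(x^2) - e_sub) / sum(x^2), 1e-5)
    a <- 2.3; b <- -0.7
    sbl <- dwt3(a * x + b * y)
    sbx <- dwt3(x); sby <- dwt3(y)
    for (nm in waveseg:::SUBBAND_NAMES)
      expect_lt(max(abs(sbl[[nm]] - a * sbx[[nm]] - b * sby[[nm]])), 1e-6)
  })
})

test_that("invalid wavelet inputs are rejected", {
  expect_error(dwt3(array(1, dim = c(4, 4, 4)), "sym9"), class = "waveseg_config")
  expect_error(dwt3(numeric(0)), class = "waveseg_invalid_argument")
  sb <- dwt3(array(rnorm(64), dim = c(4, 4, 4)))
  sb$hll <- sb$hll[1, , , drop = FALSE]
  expect_error(idwt3(sb), class = "waveseg_invalid_argument")
})

test_that("batched transforms act channel-wise with no cross-talk", {
  withr::with_seed(10, {
    stack <- array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4))
    sets <- batched_dwt3(stack)
    expect_length(sets, 4)
    one <- dwt3(stack[, , , 2])
    expect_equal(sets[[2]]$lll, one$lll, tolerance = 1e-12)
    # channel permutation equivariance
    perm <- c(3, 1, 4, 2)
    sets_p <- batched_dwt3(stack[, , , perm])
    for (i in 1:4)
      expect_equal(sets_p[[i]]$hhh, sets[[perm[i]]]$hhh, tolerance = 1e-12)
    # round trip
    expect_lt(max(abs(batched_idwt3(sets) - stack)), 1e-5)
  })
})
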