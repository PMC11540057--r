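tiny_cfg <- function(base = 4L) model_config(base_channels = base)

test_that("residual block passes the input through when weights are zero", {
  C <- 4L
  p <- waveseg:::res_block_params(C, C, "blk")
  for (nm in grep("conv", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  x <- array(rnorm(6 * 6 * 6 * C), dim = c(6, 6, 6, C))
  P <- lapply(p, waveseg:::ad_leaf)
  out <- waveseg:::ad_res_block(waveseg:::ad_leaf(x), P, "blk", 2L)
  expect_equal(waveseg:::ad_value(out), x, tolerance = 1e-12)
  # zero input with zero biases stays zero even with random weights
  p2 <- waveseg:::res_block_params(C, 2L * C, "blk")
  z <- array(0, dim = c(6, 6, 6, C))
  out2 <- waveseg:::ad_res_block(waveseg:::ad_leaf(z), lapply(p2, waveseg:::ad_leaf),
                                 "blk", 2L)
  expect_lt(max(abs(waveseg:::ad_value(out2))), 1e-10)
})

test_that("forward pass obeys the shape/range contract and is deterministic", {
  cfg <- tiny_cfg()
  params <- init_model(cfg, seed = 1)
  x <- withr::with_seed(30, array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4)))
  out <- net_forward(params, x, cfg)
  expect_equal(dim(out$probabilities), c(16, 16, 16, 3))
  expect_true(all(out$probabilities >= 0 & out$probabilities <= 1))
  expect_equal(out$probabilities, 1 / (1 + exp(-out$logits)), tolerance = 1e-12)
  out2 <- net_forward(params, x, cfg)
  expect_identical(out$probabilities, out2$probabilities)
  expect_error(net_forward(params, x[1:15, , , , drop = FALSE], cfg),
               class = "waveseg_shape")
})

test_that("zeroed weights propagate to a spatially constant head output", {
  cfg <- tiny_cfg()
  params <- lapply(init_model(cfg, seed = 1), function(p) p * 0)
  # group-norm scale must stay 1 to be a valid 'zero feature' path
  x <- withr::with_seed(31, array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4)))
  out <- net_forward(params, x, cfg)
  pm <- matrix(out$probabilities, ncol = 3)
  for (r in 1:3) expect_lt(diff(range(pm[, r])), 1e-10)
  expect_equal(pm[1, ], rep(0.5, 3), tolerance = 1e-12)  # sigmoid(0)
})

test_that("encoder branches have disjoint, modality-specific weights", {
  cfg <- tiny_cfg()
  params <- init_model(cfg, seed = 1)
  n1 <- grep("^enc1\\.", names(params), value = TRUE)
  n2 <- grep("^enc2\\.", names(params), value = TRUE)
  expect_length(intersect(n1, n2), 0)
  expect_equal(length(n1), length(n2))
  # same architecture, independent draws
  expect_false(isTRUE(all.equal(params[["enc1.l1.res.conv1.w"]],
                                params[["enc2.l1.res.conv1.w"]])))
  # perturbing one branch changes the output (no hidden sharing)
  x <- withr::with_seed(32, array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4)))
  base <- net_forward(params, x, cfg)$probabilities
  params[["enc3.l2.res.conv1.w"]] <- params[["enc3.l2.res.conv1.w"]] + 0.5
  expect_gt(max(abs(net_forward(params, x, cfg)$probabilities - base)), 0)
})

test_that("every parameter receives gradient on a random batch", {
  # 32^3 input so the deepest level spans 8 positions: attention keys only
  # influence the softmax when there is more than one position to weigh.
  cfg <- tiny_cfg()
  params <- init_model(cfg, seed = 2, gcam_zero_init = FALSE)
  x <- withr::with_seed(33, array(rnorm(32^3 * 4), dim = c(32, 32, 32, 4)))
  u <- withr::with_seed(34, array(rbinom(32^3 * 3, 1, 0.3), dim = c(32, 32, 32, 3)))
  P <- lapply(params, waveseg:::ad_leaf, requires_grad = TRUE)
  out <- waveseg:::net_graph(P, x, cfg)
  loss <- waveseg:::ad_bce_dice_loss(out$probs, u)
  waveseg:::ad_backward(loss)
  dead <- names(P)[vapply(P, function(n)
    is.null(n$grad) || all(n$grad == 0), logical(1))]
  expect_length(dead, 0)
})

test_that("parameter counting matches closed-form block formulas", {
  cfg <- tiny_cfg(base = 8L)
  tab <- count_parameters(cfg)
  total <- attr(tab, "total")
  expect_equal(total, sum(tab$parameters))
  # attention blocks match the closed form
  g4 <- tab$parameters[tab$block == "enc1.l4.gcam"]
  expect_equal(g4, gcam_param_count(64, cfg$gcam_ratio))
  g5 <- tab$parameters[tab$block == "enc1.l5.gcam"]
  expect_equal(g5, gcam_param_count(128, cfg$gcam_ratio))
  # an equal-width residual block holds 2*(27 C^2 + C) conv + 4 C norm params
  C <- 16L
  blk <- tab$parameters[tab$block == "enc1.l2.res"]
  expect_equal(blk, 2 * (27 * C * C + C) + 4 * C)
  # doubling the base exactly quadruples the conv-weight share of the block
  tab2 <- count_parameters(tiny_cfg(base = 16L))
  C2 <- 32L
  blk2 <- tab2$parameters[tab2$block == "enc1.l2.res"]
  expect_equal(blk2 - 6 * C2, 4 * (blk - 6 * C))   # strip biases + norm affine
  expect_error(model_config(num_levels = 0L), class = "waveseg_config")
})
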