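small_train_setup <- function(n = 3, seed = 61L) {
  vols <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(volume_shape = c(16, 16, 16),
                                  region_radii = c(5, 3, 1.5),
                                  noise_sd = 1, seed = seed + i)))
  cfg <- train_config(lr = 1e-3, epochs = 2L, crop_size = NULL,
                      augment = FALSE, validate = FALSE, seed = 5L,
                      model = model_config(base_channels = 2L, norm_groups = 2L))
  list(vols = vols, cfg = cfg)
}

test_that("polynomial decay follows lr0 * (1 - t/T)^power", {
  expect_equal(poly_lr(1e-5, 50, 100, 0.9), 1e-5 * 0.5^0.9, tolerance = 1e-12)
  expect_equal(poly_lr(1e-5, 50, 100, 0.9), 5.359e-6, tolerance = 1e-3)
  expect_equal(poly_lr(2e-4, 0, 10), 2e-4)
  expect_lt(poly_lr(1e-5, 99, 100), poly_lr(1e-5, 1, 100))
})

test_that("a tiny training run logs decreasing loss and round-trips checkpoints", {
  st <- small_train_setup()
  model <- train_model(st$vols, st$cfg)
  expect_s3_class(model, "waveseg_model")
  expect_equal(nrow(model$log), 2 * 3)
  expect_lt(model$log$loss[nrow(model$log)], model$log$loss[1])
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  re <- load_checkpoint(ck)
  v <- zscore_normalize(st$vols[[1]])
  p1 <- net_forward(model$params, v$channels, model$config$model)
  p2 <- net_forward(re$params, v$channels, re$config$model)
  expect_identical(p1$probabilities, p2$probabilities)
})

test_that("training with a validation split tracks the best checkpoint", {
  st <- small_train_setup(n = 4)
  cfg <- st$cfg
  cfg$validate <- TRUE
  model <- train_model(st$vols, cfg)
  expect_true(is.finite(model$best_val_dice))
  expect_gt(model$best_val_dice, 0)
})

test_that("prediction emits valid BraTS labels and honours post-processing scope", {
  st <- small_train_setup()
  model <- train_model(st$vols, st$cfg)
  vol <- st$vols[[1]]
  pred_off <- predict_volume(model, vol, postprocess = FALSE)
  expect_true(all(pred_off$labels %in% c(0L, 1L, 2L, 4L)))
  expect_equal(dim(pred_off$labels), dim(vol$labels))
  pred_on <- predict_volume(model, vol, postprocess = TRUE)
  changed <- pred_off$labels != pred_on$labels
  expect_true(all(pred_off$labels[changed] %in% c(1L, 4L)))
  expect_true(all(pred_on$labels[changed] %in% c(1L, 4L)))
  # nesting always holds after decoding
  rm <- encode_regions(pred_off$labels)
  expect_true(all(rm$et <= rm$tc) && all(rm$tc <= rm$wt))
})

test_that("volumes with awkward extents are padded transparently at inference", {
  st <- small_train_setup(n = 2)
  model <- train_model(st$vols, st$cfg)
  vol <- st$vols[[1]]
  crop <- function(v, n) {
    v$channels <- v$channels[1:n, , , , drop = FALSE]
    v$labels <- v$labels[1:n, , , drop = FALSE]
    v
  }
  odd <- crop(vol, 13)
  pred <- predict_volume(model, odd)
  expect_equal(dim(pred$labels), c(13, 16, 16))
})

test_that("configurations survive a YAML round trip", {
  cfg <- train_config(lr = 3e-4, epochs = 7L, crop_size = c(32L, 32L, 32L),
                      model = model_config(base_channels = 8L, gcam_ratio = 2L),
                      loss = loss_config(epsilon = 1e-4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$lr, cfg$lr)
  expect_equal(cfg2$epochs, cfg$epochs)
  expect_equal(cfg2$model$channel_schedule, cfg$model$channel_schedule)
  expect_equal(cfg2$model$gcam_ratio, 2L)
  expect_equal(cfg2$loss$epsilon, 1e-4)
})

test_that("non-finite losses abort with a diagnostic instead of silently diverging", {
  st <- small_train_setup(n = 2)
  cfg <- st$cfg
  cfg$normalize <- FALSE
  st$vols[[1]]$channels[1, 1, 1, 1] <- NaN   # corrupt voxel reaches the loss
  st$vols[[2]]$channels[1, 1, 1, 1] <- NaN
  err <- expect_error(train_model(st$vols, cfg), class = "waveseg_nan")
  expect_match(conditionMessage(err), "epoch")
})
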