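test_that("zero-contrast, zero-noise spec yields all-zero channels with nested labels", {
  spec <- phantom_spec(volume_shape = c(32, 32, 32), region_radii = c(8, 5, 2),
                       noise_sd = 0, seed = 4L,
                       modality_contrast = lapply(default_contrast(), function(x) x * 0))
  vol <- generate_phantom(spec)
  expect_true(all(vol$channels == 0))
  rm <- encode_regions(vol$labels)
  expect_true(all(rm$et <= rm$tc))
  expect_true(all(rm$tc <= rm$wt))
  expect_gt(sum(rm$et), 0)
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- tiny_phantom_spec(seed = 11L, noise_sd = 3)
  v1 <- generate_phantom(spec)
  v2 <- generate_phantom(spec)
  expect_identical(v1$channels, v2$channels)
  expect_identical(v1$labels, v2$labels)
})

test_that("enhancing-tumor voxel count matches an independent ellipsoid scan", {
  spec <- phantom_spec(volume_shape = c(64, 64, 64), region_radii = c(12, 8, 4),
                       noise_sd = 0, seed = 9L)
  vol <- generate_phantom(spec)
  ce <- vol$tumor_center
  grid <- expand.grid(x = 1:64, y = 1:64, z = 1:64)
  d2 <- function(r) ((grid$x - ce[1])^2 + (grid$y - ce[2])^2 +
                     (grid$z - ce[3])^2) / r^2
  n4_oracle <- sum(d2(8) <= 1 & d2(4) > 1)
  expect_equal(sum(vol$labels == 4L), n4_oracle)
})

test_that("default contrasts give the expected modality-specific appearance", {
  vol <- generate_phantom(tiny_phantom_spec(seed = 5L, noise_sd = 2))
  flair <- vol$channels[, , , "flair"]
  t1ce <- vol$channels[, , , "t1ce"]
  brain <- vol$labels == 0L & flair != 0
  expect_gt(mean(flair[vol$labels == 2L]), mean(flair[brain]))
  expect_gt(mean(t1ce[vol$labels == 4L]), mean(t1ce[vol$labels == 1L]))
})

test_that("noise-free phantom is piecewise constant per modality and region", {
  vol <- generate_phantom(tiny_phantom_spec(seed = 2L, noise_sd = 0))
  for (m in 1:4) {
    ch <- vol$channels[, , , m]
    for (lab in c(1L, 2L, 4L))
      expect_length(unique(ch[vol$labels == lab]), 1)
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(region_radii = c(5, 8, 2)), class = "waveseg_invalid_spec")
  expect_error(phantom_spec(volume_shape = c(8, 8, 8)), class = "waveseg_invalid_spec")
  expect_error(phantom_spec(volume_shape = c(17, 32, 32)), class = "waveseg_invalid_spec")
  expect_error(phantom_spec(region_radii = c(30, 20, 10)), class = "waveseg_invalid_spec")
})

test_that("generate_dataset writes the BraTS layout and a usable manifest", {
  out <- withr::local_tempdir()
  spec <- tiny_phantom_spec(seed = 21L, noise_sd = 1)
  man <- generate_dataset(2, spec, out)
  expect_length(man$cases, 2)
  files <- list.files(out, pattern = "\\.nii\\.gz$", recursive = TRUE)
  expect_length(files, 10)   # 4 modalities + seg per case
  # round trip
  v0 <- generate_phantom(spec)
  rt <- read_case(man$cases[[1]]$dir)
  expect_equal(as.numeric(rt$channels), as.numeric(v0$channels), tolerance = 1e-6)
  expect_identical(as.integer(rt$labels), as.integer(v0$labels))
  # manifest readable
  m2 <- read_manifest(man$manifest_path)
  expect_equal(m2$n, 2)
})

test_that("distinct per-case seeds give pairwise distinct phantoms", {
  out <- withr::local_tempdir()
  man <- generate_dataset(5, tiny_phantom_spec(seed = 31L, noise_sd = 1), out)
  labs <- lapply(man$cases, function(cs) read_case(cs$dir)$labels)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(labs[[i]], labs[[j]]))
})
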