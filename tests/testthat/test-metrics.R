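test_that("Dice follows the confusion-count definition and its conventions", {
  m <- array(FALSE, dim = c(6, 6, 6))
  a <- m; a[1:5] <- TRUE
  expect_equal(dice_score(a, a), 1)
  b <- m; b[10:14] <- TRUE
  expect_equal(dice_score(a, b), 0)
  # TP = 3, FP = 1, FN = 2 -> 6/9
  tr <- m; tr[1:5] <- TRUE
  pr <- m; pr[2:4] <- TRUE; pr[20] <- TRUE
  expect_equal(dice_score(pr, tr), 2 / 3, tolerance = 1e-12)
  expect_equal(dice_score(pr, tr), dice_score(tr, pr))
  expect_equal(dice_score(m, m), 1)        # both empty
  # adding a true positive never decreases the score
  pr2 <- pr; pr2[5] <- TRUE
  expect_gte(dice_score(pr2, tr), dice_score(pr, tr))
  expect_error(dice_score(a, array(FALSE, c(2, 2, 2))),
               class = "waveseg_invalid_argument")
})

test_that("percentile Hausdorff handles point masks and empty-mask conventions", {
  m <- array(FALSE, dim = c(10, 10, 10))
  a <- m; a[2, 5, 5] <- TRUE
  b <- m; b[5, 5, 5] <- TRUE
  expect_equal(hd95(a, b), 3)
  expect_equal(hd95(a, a), 0)
  expect_equal(hd95(m, m), 0)              # both empty
  expect_equal(hd95(a, m), 373.13)         # exactly one empty
  expect_equal(hd95(m, a), 373.13)
  # anisotropic spacing scales the distance
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)
})

test_that("Hausdorff distances match the all-pairs oracle on random blobs", {
  for (seed in 1:3) {
    p <- random_blob(c(14, 14, 14), seed = seed)
    q <- random_blob(c(14, 14, 14), seed = seed + 50)
    expect_lte(sum(surface_voxels(p)), 500)
    expect_lt(abs(hd95(p, q) - hd95_oracle(p, q)), 1e-6)
    expect_lt(abs(hd95(p, q, percentile = 100) -
                  hd95_oracle(p, q, percentile = 100)), 1e-6)
    expect_equal(hd95(p, q), hd95(q, p), tolerance = 1e-12)
  }
})

test_that("Hausdorff is invariant under joint translations", {
  p <- random_blob(c(16, 16, 16), seed = 7)
  q <- random_blob(c(16, 16, 16), seed = 77)
  shift <- function(m) {
    out <- array(FALSE, dim = dim(m))
    out[3:16, 2:16, 1:16] <- m[1:14, 1:15, 1:16]
    out
  }
  expect_equal(hd95(shift(p), shift(q)), hd95(p, q), tolerance = 1e-10)
})

test_that("small-ET relabelling is strict at the threshold and WT-preserving", {
  base <- array(0L, dim = c(12, 12, 12))
  base[1:50] <- 2L
  with199 <- base; with199[101:299] <- 4L
  out <- postprocess_et(with199)
  expect_equal(sum(out == 4L), 0)
  expect_equal(sum(out == 1L), 199)
  with200 <- base; with200[101:300] <- 4L
  expect_identical(postprocess_et(with200), with200)   # strictly fewer only
  expect_identical(postprocess_et(base), base)         # no ET at all
  # WT and TC membership unchanged
  rm_in <- encode_regions(with199)
  rm_out <- encode_regions(out)
  expect_identical(rm_in$wt, rm_out$wt)
  expect_identical(rm_in$tc, rm_out$tc)
})

test_that("per-component relabelling only clears small components", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[1:3, 1:3, 1:3] <- 4L                 # 27 voxels
  lab[10:16, 10:16, 10:16] <- 4L           # 343 voxels
  out <- postprocess_et(lab, threshold = 200, per_component = TRUE)
  expect_equal(sum(out == 4L), 343)
  expect_equal(sum(out == 1L), 27)
})

test_that("case evaluation composes the scalar metrics and aggregates", {
  td <- withr::local_tempdir()
  pd <- file.path(td, "pred"); gd <- file.path(td, "truth")
  man <- generate_dataset(3, tiny_phantom_spec(seed = 41L, noise_sd = 1), gd)
  dir.create(pd)
  labs <- lapply(man$cases, function(cs) read_case(cs$dir)$labels)
  # case 1: perfect; case 2: perturbed; case 3: perfect
  pert <- labs[[2]]
  idx <- which(pert == 2L)[1:20]
  pert[idx] <- 0L
  preds <- list(labs[[1]], pert, labs[[3]])
  for (i in 1:3)
    RNifti::writeNifti(preds[[i]],
                       file.path(pd, sprintf("case_%04d_seg.nii.gz", i)),
                       datatype = "int16")
  rep <- evaluate_cases(pd, gd)
  expect_true(rep$complete)
  pc <- rep$per_case
  expect_equal(nrow(pc), 9)
  expect_true(all(pc$dice[pc$case != "case_0002"] == 1))
  expect_true(all(pc$hd95[pc$case != "case_0002"] == 0))
  # single-case values equal the scalar operations
  r2 <- encode_regions(labs[[2]]); p2 <- encode_regions(pert)
  expect_equal(pc$dice[pc$case == "case_0002" & pc$region == "WT"],
               dice_score(p2$wt, r2$wt))
  expect_equal(pc$hd95[pc$case == "case_0002" & pc$region == "WT"],
               hd95(p2$wt, r2$wt))
  # aggregate mean equals the hand-computed average
  wt_mean <- mean(pc$dice[pc$region == "WT"])
  expect_equal(rep$summary$mean[rep$summary$region == "WT" &
                                rep$summary$metric == "dice"], wt_mean)
  # a missing prediction is reported, not fatal
  file.remove(file.path(pd, "case_0003_seg.nii.gz"))
  rep2 <- evaluate_cases(pd, gd)
  expect_false(rep2$complete)
  expect_equal(rep2$missing, "case_0003")
})
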