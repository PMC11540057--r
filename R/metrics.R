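#' Dice similarity coefficient
#'
#' `Dice = 2TP / (2TP + FP + FN)` between two binary masks.  When both masks
#' are empty the score is 1 by convention.
#'
#' @param pred logical/0-1 array, the prediction.
#' @param truth logical/0-1 array, the reference, same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_waveseg("waveseg_invalid_argument", "mask shapes differ")
  p <- as.logical(pred); q <- as.logical(truth)
  tp <- sum(p & q)
  fp <- sum(p & !q)
  fn <- sum(!p & q)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Surface voxels of a binary mask
#'
#' Foreground voxels with at least one 6-connected background neighbour;
#' voxels on the array border count as surface.
#'
#' @param mask logical 3D array.
#' @return logical 3D array marking the surface.
#' @export
surface_voxels <- function(mask) {
  m <- as.array(mask)
  storage.mode(m) <- "logical"
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, axis, by) {
    idx <- lapply(d, seq_len)
    src <- lapply(d, seq_len)
    if (by == 1) { idx[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else { idx[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    nb <- array(FALSE, dim = d)
    nb[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (axis in 1:3) for (by in c(1, -1))
    interior <- shift_and(interior, axis, by)
  m & !interior
}

#' Percentile Hausdorff distance between two masks
#'
#' Symmetric percentile (default 95th) of the directed surface distances
#' between two binary masks, in physical units.  Directed distances are
#' measured from the surface voxels of one mask to the nearest surface voxel
#' of the other via an exact Euclidean distance transform.  Conventions for
#' empty masks follow common evaluation-platform practice: both empty gives
#' 0, exactly one empty gives the sentinel (default 373.13 mm).
#' `percentile = 100` recovers the classical Hausdorff distance.
#'
#' @param pred,truth binary 3D arrays of one shape.
#' @param spacing voxel spacing in mm, length 3.
#' @param percentile percentile of the directed distance distributions.
#' @param empty_sentinel value returned when exactly one mask is empty.
#' @param surface_only measure from surface voxels (default) or from all
#'   foreground voxels.
#' @return distance in mm.
#' @export
hd95 <- function(pred, truth, spacing = c(1, 1, 1), percentile = 95,
                 empty_sentinel = 373.13, surface_only = TRUE) {
  if (!identical(dim(pred), dim(truth)))
    stop_waveseg("waveseg_invalid_argument", "mask shapes differ")
  p <- as.logical(pred); dim(p) <- dim(pred)
  q <- as.logical(truth); dim(q) <- dim(truth)
  np <- sum(p); nq <- sum(q)
  if (np == 0 && nq == 0) return(0)
  if (np == 0 || nq == 0) return(empty_sentinel)
  ps <- if (surface_only) surface_voxels(p) else p
  qs <- if (surface_only) surface_voxels(q) else q
  dq <- cpp_edt(as.logical(qs), dim(q), as.numeric(spacing))
  dp <- cpp_edt(as.logical(ps), dim(p), as.numeric(spacing))
  d_pq <- dq[ps]   # distance from every P-surface voxel to Q's surface
  d_qp <- dp[qs]
  max(stats::quantile(d_pq, percentile / 100, names = FALSE, type = 7),
      stats::quantile(d_qp, percentile / 100, names = FALSE, type = 7))
}

#' Relabel small enhancing-tumor predictions to necrosis
#'
#' Champion-protocol post-processing: if the total number of enhancing-tumor
#' voxels (label 4) is strictly smaller than `threshold`, every label-4 voxel
#' is relabelled to necrosis (label 1); otherwise the volume is unchanged.
#' Other labels are never touched, so whole-tumor and tumor-core membership
#' are preserved.  A per-connected-component variant is available via
#' `per_component = TRUE`.
#'
#' @param labels integer label volume with values in \{0, 1, 2, 4\}.
#' @param threshold voxel-count threshold (default 200, strict `<`).
#' @param per_component apply the rule per 6-connected ET component instead
#'   of to the total count.
#' @return the post-processed label volume.
#' @export
postprocess_et <- function(labels, threshold = 200L, per_component = FALSE) {
  check_labels(labels)
  if (!per_component) {
    if (sum(labels == 4L) < threshold)
      labels[labels == 4L] <- 1L
    return(labels)
  }
  comp <- label_components(labels == 4L)
  if (comp$n > 0)
    for (k in seq_len(comp$n)) {
      idx <- comp$labels == k
      if (sum(idx) < threshold) labels[idx] <- 1L
    }
  labels
}

# 6-connected component labelling (BFS), small volumes only.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  n <- 0L
  idx_all <- which(mask)
  if (length(idx_all) == 0) return(list(labels = lab, n = 0L))
  coords <- arrayInd(idx_all, d)
  key <- function(co) (co[, 1] - 1) + d[1] * ((co[, 2] - 1) + d[2] * (co[, 3] - 1)) + 1
  inmask <- logical(prod(d)); inmask[idx_all] <- TRUE
  visited <- logical(prod(d))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in idx_all) {
    if (visited[s]) next
    n <- n + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      lab[cur] <- n
      co <- arrayInd(cur, d)
      for (o in seq_len(6)) {
        nb <- co + offs[o, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        ni <- key(nb)
        if (inmask[ni] && !visited[ni]) {
          visited[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
  }
  list(labels = lab, n = n)
}

#' Evaluate predicted segmentations against reference labels
#'
#' Computes per-case and aggregate Dice and percentile-Hausdorff scores for
#' the three nested regions.  Prediction and truth directories must contain
#' `<case>_seg.nii.gz` files (BraTS layout, one sub-directory per case, or
#' flat files); cases present in the truth but missing a prediction are
#' listed in the report rather than failing the run.
#'
#' @param pred_dir directory of predicted label volumes.
#' @param truth_dir directory of reference label volumes.
#' @param spacing voxel spacing in mm.
#' @param csv_path optional path; when given, the per-case table is written
#'   as CSV.
#' @return an `eval_report`: list with `per_case` (data.frame), `summary`
#'   (data.frame with mean/median/IQR and outlier counts per region/metric),
#'   `outliers`, and `missing`.
#' @export
evaluate_cases <- function(pred_dir, truth_dir, spacing = c(1, 1, 1),
                           csv_path = NULL) {
  find_segs <- function(dir) {
    files <- list.files(dir, pattern = "_seg\\.nii(\\.gz)?$",
                        recursive = TRUE, full.names = TRUE)
    ids <- sub("_seg\\.nii(\\.gz)?$", "", basename(files))
    stats::setNames(files, ids)
  }
  truth_files <- find_segs(truth_dir)
  pred_files <- find_segs(pred_dir)
  if (length(truth_files) == 0)
    stop_waveseg("waveseg_io", "no reference segmentations in '%s'", truth_dir)
  missing <- setdiff(names(truth_files), names(pred_files))
  common <- intersect(names(truth_files), names(pred_files))
  rows <- list()
  for (id in common) {
    tr <- as.array(RNifti::readNifti(truth_files[[id]]))
    pr <- as.array(RNifti::readNifti(pred_files[[id]]))
    storage.mode(tr) <- "integer"; storage.mode(pr) <- "integer"
    rt <- encode_regions(tr); rp <- encode_regions(pr)
    for (reg in c("wt", "tc", "et")) {
      rows[[length(rows) + 1]] <- data.frame(
        case = id, region = toupper(reg),
        dice = dice_score(rp[[reg]], rt[[reg]]),
        hd95 = hd95(rp[[reg]], rt[[reg]], spacing))
    }
  }
  per_case <- do.call(rbind, rows)
  summarise <- function(x) {
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    out <- x < qs[1] - 1.5 * iqr | x > qs[3] + 1.5 * iqr
    c(mean = mean(x), median = qs[2], q1 = qs[1], q3 = qs[3],
      iqr = iqr, n_outliers = sum(out))
  }
  summ <- do.call(rbind, lapply(split(per_case, per_case$region), function(df) {
    data.frame(region = df$region[1],
               metric = c("dice", "hd95"),
               rbind(summarise(df$dice), summarise(df$hd95)))
  }))
  rownames(summ) <- NULL
  outliers <- do.call(rbind, lapply(split(per_case, per_case$region), function(df) {
    qs <- stats::quantile(df$dice, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    df[df$dice < qs[1] - 1.5 * iqr | df$dice > qs[2] + 1.5 * iqr, , drop = FALSE]
  }))
  if (!is.null(csv_path)) write.csv(per_case, csv_path, row.names = FALSE)
  structure(list(per_case = per_case, summary = summ,
                 outliers = outliers, missing = missing,
                 complete = length(missing) == 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d case-region rows%s\n", nrow(x$per_case),
              if (x$complete) "" else sprintf(" (%d case(s) missing predictions)",
                                              length(x$missing))))
  print(x$summary, digits = 4)
  invisible(x)
}
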