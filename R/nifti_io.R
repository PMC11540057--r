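#' Write a multimodal case in BraTS layout
#'
#' Writes `<case>_{t1,t1ce,t2,flair}.nii.gz` and, when labels are present,
#' `<case>_seg.nii.gz` into `case_dir`.
#'
#' @param vol a `multimodal_volume`.
#' @param case_dir directory for the case (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_case <- function(vol, case_dir) {
  stopifnot(inherits(vol, "multimodal_volume"))
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(case_dir))
    stop_waveseg("waveseg_io", "cannot create case directory '%s'", case_dir)
  paths <- character(0)
  for (m in seq_along(MODALITIES)) {
    p <- file.path(case_dir, sprintf("%s_%s.nii.gz", vol$case_id, MODALITIES[m]))
    RNifti::writeNifti(structure(vol$channels[, , , m],
                                 pixdim = vol$spacing), p)
    paths <- c(paths, p)
  }
  if (!is.null(vol$labels)) {
    p <- file.path(case_dir, sprintf("%s_seg.nii.gz", vol$case_id))
    RNifti::writeNifti(structure(vol$labels, pixdim = vol$spacing), p,
                       datatype = "int16")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a multimodal case from a BraTS-style directory
#'
#' Expects `<case>_{t1,t1ce,t2,flair}.nii.gz` (and optionally
#' `<case>_seg.nii.gz`) inside `case_dir`; the case id is inferred from the
#' directory name unless given.
#'
#' @param case_dir path to the case directory.
#' @param case_id optional explicit case identifier.
#' @return a `multimodal_volume`.
#' @export
read_case <- function(case_dir, case_id = basename(case_dir)) {
  paths <- file.path(case_dir, sprintf("%s_%s.nii.gz", case_id, MODALITIES))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop_waveseg("waveseg_io", "missing modality file(s): %s",
                 paste(missing, collapse = ", "))
  imgs <- lapply(paths, RNifti::readNifti)
  shp <- dim(imgs[[1]])
  channels <- array(0, dim = c(shp, 4))
  dimnames(channels) <- list(NULL, NULL, NULL, MODALITIES)
  for (m in seq_len(4)) channels[, , , m] <- as.array(imgs[[m]])
  seg_path <- file.path(case_dir, sprintf("%s_seg.nii.gz", case_id))
  labels <- NULL
  if (file.exists(seg_path)) {
    labels <- as.array(RNifti::readNifti(seg_path))
    storage.mode(labels) <- "integer"
  }
  spacing <- as.numeric(RNifti::pixdim(imgs[[1]]))[1:3]
  multimodal_volume(channels, labels, spacing = spacing, case_id = case_id)
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path path to `manifest.json`.
#' @return the manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_waveseg("waveseg_io", "manifest not found: %s", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
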