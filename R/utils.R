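#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_waveseg <- function(class, msg, ...) {
  stop(structure(class = c(class, "waveseg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_labels <- function(labels) {
  vals <- unique(as.integer(labels))
  bad <- setdiff(vals, BRATS_LABELS)
  if (length(bad) > 0)
    stop_waveseg("waveseg_invalid_label",
                 "invalid label value(s): %s (expected subset of {0,1,2,4})",
                 paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}
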