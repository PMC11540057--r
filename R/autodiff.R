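# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Nodes are environments holding a value, an accumulated gradient, their
# parent nodes and a backward closure that maps the node's gradient to a list
# of parent gradients.  Node creation order (a monotone id) gives a valid
# topological order, so backpropagation is a single reverse sweep.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_next_id <- function() {
  .ad$counter <- .ad$counter + 1L
  .ad$counter
}

#' Create an autodiff leaf node
#'
#' @param value numeric array or scalar.
#' @param requires_grad should gradients be accumulated for this node?
#' @return an `ad_node`.
#' @keywords internal
ad_leaf <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backward <- NULL
  e$requires_grad <- requires_grad
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

ad_op <- function(value, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# Reverse sweep from a scalar loss node; leaves gradients in node$grad.
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"), length(loss$value) == 1)
  nodes <- new.env(parent = emptyenv())
  collect <- function(n) {
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) return(invisible(NULL))
    nodes[[key]] <- n
    for (p in n$parents) if (p$requires_grad || length(p$parents)) collect(p)
  }
  collect(loss)
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  loss$grad <- 1
  for (id in ids) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$grad) || is.null(n$backward)) next
    if (!n$requires_grad) next
    pgrads <- n$backward(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      g <- pgrads[[i]]
      if (is.null(g)) next
      if (!p$requires_grad && length(p$parents) == 0) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (id != loss$id) n$grad <- NULL   # free activation gradients early
  }
  invisible(loss)
}
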