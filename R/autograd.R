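# Reverse-mode automatic differentiation over plain R arrays.
#
# A tensor is an environment holding a value array, an accumulated gradient,
# its parent tensors and a backward closure mapping the output gradient to
# per-parent gradients. Graphs are built dynamically; backward() walks the
# tape in reverse creation order.

.mt <- new.env(parent = emptyenv())
.mt$counter <- 0
.mt$training <- FALSE

#' Create a tensor
#'
#' Wraps a numeric array as a node of the automatic-differentiation graph.
#'
#' @param v numeric vector, matrix or array.
#' @param req logical; does this leaf require a gradient (i.e. is it a
#'   learnable parameter)?
#' @param name optional label used in diagnostics.
#' @return an object of class `mt_tensor`.
#' @keywords internal
#' @export
tsr <- function(v, req = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- list()
  e$bw <- NULL
  e$req <- req
  e$name <- name
  .mt$counter <- .mt$counter + 1
  e$nid <- .mt$counter
  class(e) <- "mt_tensor"
  e
}

is_tsr <- function(x) inherits(x, "mt_tensor")

# internal node constructor: bw(grad) must return a list of gradients, one
# per parent (NULL allowed for parents that need none)
tn_node <- function(v, parents, bw) {
  req <- any(vapply(parents, function(p) p$req, logical(1)))
  e <- tsr(v, req = req)
  if (req) {
    e$parents <- parents
    e$bw <- bw
  }
  e
}

#' Tensor value
#' @param x an `mt_tensor`.
#' @return the wrapped numeric array.
#' @keywords internal
#' @export
val <- function(x) x$v

#' @export
print.mt_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$req) "grad" else "", ">\n")
  invisible(x)
}

#' Backpropagate from a scalar loss
#'
#' Accumulates gradients into every reachable tensor created with
#' `req = TRUE` (and intermediates that need them).
#'
#' @param loss a scalar `mt_tensor`.
#' @keywords internal
#' @export
backward <- function(loss) {
  stopifnot(is_tsr(loss), length(loss$v) == 1)
  # collect reachable subgraph
  nodes <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$nid)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- nd
    for (p in nd$parents) if (p$req) stack[[length(stack) + 1L]] <- p
  }
  ids <- sort(as.numeric(ls(nodes)), decreasing = TRUE)
  loss$grad <- if (is.null(dim(loss$v))) 1 else array(1, dim = dim(loss$v))
  for (id in ids) {
    nd <- nodes[[as.character(id)]]
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$req || is.null(gs[[i]])) next
      if (is.null(p$grad)) p$grad <- gs[[i]] else p$grad <- p$grad + gs[[i]]
    }
    # free intermediate gradients (keep leaves')
    if (length(nd$parents)) nd$grad <- NULL
  }
  invisible(NULL)
}

#' Reset gradients of a parameter list
#' @param params list of `mt_tensor`s.
#' @keywords internal
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Switch between training and evaluation mode
#'
#' Batch-normalization layers use batch statistics in training mode and
#' running statistics in evaluation mode.
#'
#' @param on logical.
#' @return the previous mode, invisibly.
#' @export
training_mode <- function(on = TRUE) {
  old <- .mt$training
  .mt$training <- isTRUE(on)
  invisible(old)
}

is_training <- function() .mt$training

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seeds through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
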