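# Reverse-mode tape over dense R arrays.
#
# A tensor is an environment holding a value (`v`, an R array), an optional
# accumulated gradient (`grad`), its parents on the tape and a backward
# closure mapping the node's gradient to one gradient per parent. Ops only
# record tape entries when gradients are enabled and some input requires
# them, so inference builds no graph.

.msli <- new.env(parent = emptyenv())
.msli$grad_enabled <- TRUE
.msli$single <- FALSE
.msli$id <- 0L

tg_grad_enabled <- function() .msli$grad_enabled

#' Evaluate an expression with gradient recording disabled
#'
#' Used for inference passes: no tape is built, so memory stays flat.
#'
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_no_grad <- function(expr) {
  old <- .msli$grad_enabled
  .msli$grad_enabled <- FALSE
  on.exit(.msli$grad_enabled <- old)
  force(expr)
}

#' Evaluate an expression with single-precision convolution kernels
#'
#' Convolutions (the dominant cost) accumulate in `float` instead of
#' `double`. All other arithmetic stays double. This is the package's
#' reduced-precision training mode.
#'
#' @param expr expression to evaluate
#' @param single logical; enable single precision
#' @return the value of `expr`
#' @export
with_single_precision <- function(expr, single = TRUE) {
  old <- .msli$single
  .msli$single <- single
  on.exit(.msli$single <- old)
  force(expr)
}

tg_new <- function(v, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$rg <- length(parents) > 0L
  e$parents <- parents
  e$bw <- bw
  .msli$id <- .msli$id + 1L
  e$id <- .msli$id
  class(e) <- "msli_tensor"
  e
}

tg_param <- function(v) {
  e <- tg_new(v)
  e$rg <- TRUE
  e
}

tg_const <- function(v) tg_new(v)

is_tensor <- function(x) inherits(x, "msli_tensor")

as_tg <- function(x) if (is_tensor(x)) x else tg_const(x)

#' @export
print.msli_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<tensor ", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$rg) " grad" else "", ">\n", sep = "")
  invisible(x)
}

tg_value <- function(x) if (is_tensor(x)) x$v else x

# TRUE when a tape entry must be recorded for these inputs.
tracking <- function(...) {
  if (!.msli$grad_enabled) return(FALSE)
  for (x in list(...)) if (is_tensor(x) && x$rg) return(TRUE)
  FALSE
}

# Make a node from a computed value; `parents` may include plain arrays,
# which are dropped from the tape.
tg_op <- function(v, parents, bw) {
  keep <- vapply(parents, function(p) is_tensor(p) && p$rg, logical(1))
  tg_new(v, parents = parents[keep], bw = function(g) bw(g)[keep])
}

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

#' Run backpropagation from a scalar loss node
#'
#' Accumulates gradients into every reachable parameter's `$grad` field.
#'
#' @param root tensor holding a scalar value
#' @keywords internal
tg_backward <- function(root) {
  stopifnot(is_tensor(root), length(root$v) == 1L)
  # iterative post-order DFS for a topological order
  topo <- vector("list", 256L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    }
  }
  root$grad <- 1.0
  for (i in seq(nt, 1L)) {
    node <- topo[[i]]
    if (is.null(node$bw) || is.null(node$grad)) next
    gs <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(node$parents[[j]], gs[[j]])
    }
    # free this node's gradient, value and backward closure (which captures
    # forward-pass arrays) as soon as they have been consumed, so peak
    # memory during backward stays close to the forward-pass footprint;
    # the root keeps its value (the loss)
    node$grad <- NULL
    if (!identical(node, root)) {
      node$v <- NULL
      node$bw <- NULL
    }
  }
  invisible(root)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
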