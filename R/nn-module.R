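# Minimal module system: a module is a mutable environment holding named
# parameter tensors (`params`), non-learned buffers (`buffers`, e.g. batch
# norm running statistics), child modules (`mods`) and a training flag.
# `forward()` dispatches on the module class.

new_module <- function(cls) {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$buffers <- list()
  e$mods <- list()
  e$training <- FALSE
  class(e) <- c(cls, "msli_module")
  e
}

#' Forward pass of a network module
#'
#' @param module a module created by one of the block constructors
#' @param x input: a numeric array `(H, W, C)` or `(H, W, C, N)` (or the
#'   module-specific input documented with its constructor), or an internal
#'   tape tensor
#' @param ... passed to methods
#' @return an object of the same kind as `x` (array in, array out)
#' @export
forward <- function(module, x, ...) UseMethod("forward")

#' Collect all parameter tensors of a module tree
#'
#' @param module a module
#' @param prefix internal; name prefix for nested parameters
#' @return named list of parameter tensors
#' @export
parameters <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$mods)) {
    out <- c(out, parameters(module$mods[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count trainable scalar parameters
#'
#' @param module a module (block or full network)
#' @return integer; total number of trainable scalars
#' @export
count_parameters <- function(module) {
  sum(vapply(parameters(module), function(p) length(p$v), numeric(1)))
}

#' Switch a module tree between training and inference mode
#'
#' Training mode makes batch normalization use batch statistics (and update
#' its running averages); inference mode uses the stored running statistics.
#'
#' @param module a module
#' @param on logical
#' @return the module, invisibly
#' @export
set_training <- function(module, on = TRUE) {
  module$training <- on
  for (m in module$mods) set_training(m, on)
  invisible(module)
}

#' Zero every learned parameter of a module tree
#'
#' Convolution weights, biases, batch-norm scales and offsets are all set to
#' zero. Used to exercise the blocks' algebraic identities.
#'
#' @param module a module
#' @return the module, invisibly
#' @export
zero_parameters <- function(module) {
  for (p in parameters(module)) p$v <- array(0, dim = dim(p$v) %||% length(p$v))
  invisible(module)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# State extraction/restoration for checkpoints: plain named lists of arrays.
module_state <- function(module, prefix = "") {
  st <- list()
  for (nm in names(module$params)) st[[paste0(prefix, nm)]] <- module$params[[nm]]$v
  for (nm in names(module$buffers)) st[[paste0(prefix, "buf.", nm)]] <- module$buffers[[nm]]
  for (nm in names(module$mods)) {
    st <- c(st, module_state(module$mods[[nm]], paste0(prefix, nm, ".")))
  }
  st
}

module_load_state <- function(module, st, prefix = "") {
  for (nm in names(module$params)) {
    key <- paste0(prefix, nm)
    if (is.null(st[[key]])) stop("checkpoint is missing parameter ", key)
    module$params[[nm]]$v <- st[[key]]
  }
  for (nm in names(module$buffers)) {
    key <- paste0(prefix, "buf.", nm)
    if (!is.null(st[[key]])) module$buffers[[nm]] <- st[[key]]
  }
  for (nm in names(module$mods)) {
    module_load_state(module$mods[[nm]], st, paste0(prefix, nm, "."))
  }
  invisible(module)
}

# Promote a single map (H,W,C) to a batch of one; remember the original rank.
as_batch <- function(x) {
  if (is_tensor(x)) return(list(x = x, squeeze = FALSE))
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("expected an array of shape (H, W, C) or (H, W, C, N)")
  }
  if (length(d) == 3L) {
    list(x = tg_const(array(x, dim = c(d, 1L))), squeeze = TRUE)
  } else {
    list(x = tg_const(x), squeeze = FALSE)
  }
}

unbatch <- function(v, squeeze) {
  if (!squeeze) return(v)
  d <- dim(v)
  array(v, dim = d[seq_len(length(d) - 1L)])
}

# Run a module on a plain array input and return a plain array.
run_module <- function(module, x, train = FALSE) {
  b <- as_batch(x)
  set_training(module, train)
  out <- if (train) forward(module, b$x) else with_no_grad(forward(module, b$x))
  unbatch(tg_value(out), b$squeeze)
}
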