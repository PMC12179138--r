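# Multi-scale dilation fusion (MDF).
#
# The block widens the receptive field with parallel 3x3 convolutions at
# dilation factors 6/12/18 on a channel-compressed copy of the input, fuses
# the branches with a skip projection, mixes channels pointwise, restores
# the channel count, and adds the result back onto the input:
#
#   F    = ReLU(BN(Conv1x1(x)))                 C -> C/2
#   Fi'  = BN(Conv1x1(BN(DilConv3x3_d(F))))     per dilation d
#   F'   = BN(Conv1x1(F))
#   Fr   = ReLU(sum_i Fi' + F')
#   y    = ReLU(BN(Conv1x1(PWConv(Fr))) + x)    C/2 -> C, post-add rectify
#
# A 3x3 kernel at dilation d covers an effective extent of 2d + 1 pixels.

#' Multi-scale dilation fusion block
#'
#' @param in_channels input channel count `C`; must be even (the internal
#'   compression to `C/2` is exact)
#' @param dilations dilation factors of the parallel branches
#' @param relu_position `"after_add"` (default) rectifies after the residual
#'   addition; `"before_add"` moves the rectification before it (ablation
#'   wiring)
#' @return an MDF module usable with [forward()] / [mdf_forward()]
#' @export
mdf_block <- function(in_channels, dilations = c(6L, 12L, 18L),
                      relu_position = c("after_add", "before_add")) {
  if (in_channels %% 2L != 0L) {
    stop("MDF requires an even channel count for exact C/2 compression, got C = ",
         in_channels)
  }
  if (any(dilations < 1L)) stop("dilation factors must be >= 1")
  m <- new_module("msli_mdf")
  m$in_channels <- as.integer(in_channels)
  m$dilations <- as.integer(dilations)
  m$relu_position <- match.arg(relu_position)
  C2 <- in_channels %/% 2L
  m$mods$compress_conv <- nn_conv2d(in_channels, C2, 1L, bias = FALSE)
  m$mods$compress_bn <- nn_batchnorm2d(C2)
  for (i in seq_along(dilations)) {
    d <- dilations[i]
    m$mods[[paste0("br", i, "_conv3")]] <-
      nn_conv2d(C2, C2, 3L, pad_h = d, dilation = d, bias = FALSE)
    m$mods[[paste0("br", i, "_bn1")]] <- nn_batchnorm2d(C2)
    m$mods[[paste0("br", i, "_conv1")]] <- nn_conv2d(C2, C2, 1L, bias = FALSE)
    m$mods[[paste0("br", i, "_bn2")]] <- nn_batchnorm2d(C2)
  }
  m$mods$skip_conv <- nn_conv2d(C2, C2, 1L, bias = FALSE)
  m$mods$skip_bn <- nn_batchnorm2d(C2)
  m$mods$pw_conv <- nn_conv2d(C2, C2, 1L, bias = FALSE)
  m$mods$expand_conv <- nn_conv2d(C2, in_channels, 1L, bias = FALSE)
  m$mods$out_bn <- nn_batchnorm2d(in_channels)
  m
}

#' @export
forward.msli_mdf <- function(module, x, ...) {
  xv <- tg_value(x)
  if (dim(xv)[3] != module$in_channels) {
    stop("MDF configured for C = ", module$in_channels,
         " channels, input has ", dim(xv)[3])
  }
  Fm <- op_relu(forward(module$mods$compress_bn,
                        forward(module$mods$compress_conv, x)))
  acc <- forward(module$mods$skip_bn, forward(module$mods$skip_conv, Fm))
  for (i in seq_along(module$dilations)) {
    h <- forward(module$mods[[paste0("br", i, "_bn1")]],
                 forward(module$mods[[paste0("br", i, "_conv3")]], Fm))
    h <- forward(module$mods[[paste0("br", i, "_bn2")]],
                 forward(module$mods[[paste0("br", i, "_conv1")]], h))
    acc <- op_add(acc, h)
  }
  Fr <- op_relu(acc)
  y <- forward(module$mods$out_bn,
               forward(module$mods$expand_conv,
                       forward(module$mods$pw_conv, Fr)))
  if (module$relu_position == "before_add") {
    op_add(op_relu(y), x)
  } else {
    op_relu(op_add(y, x))
  }
}

#' Channel compression stage of an MDF block
#'
#' Applies the block's `1x1` convolution, batch normalization and
#' rectification, halving the channel count.
#'
#' @param block an [mdf_block()]
#' @param x array `(H, W, C)` or `(H, W, C, N)` with `C = in_channels`
#' @param train logical; use batch statistics in the normalization
#' @return array with `C/2` channels, spatial size unchanged
#' @export
compress_channels <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "msli_mdf"))
  b <- as_batch(x)
  if (dim(tg_value(b$x))[3] != block$in_channels) {
    stop("MDF configured for C = ", block$in_channels,
         " channels, input has ", dim(tg_value(b$x))[3])
  }
  set_training(block, train)
  out <- with_no_grad(
    op_relu(forward(block$mods$compress_bn,
                    forward(block$mods$compress_conv, b$x))))
  unbatch(tg_value(out), b$squeeze)
}

#' Single dilated branch of an MDF block
#'
#' Runs one parallel branch (3x3 convolution at dilation `d` with padding
#' `d`, batch norm, `1x1` convolution, batch norm; no rectification) on an
#' already-compressed feature map.
#'
#' @param block an [mdf_block()]
#' @param f compressed feature map with `C/2` channels
#' @param d dilation factor; must be one of the block's `dilations`
#' @param train logical
#' @return array of the same shape as `f`
#' @export
dilated_branch <- function(block, f, d, train = FALSE) {
  stopifnot(inherits(block, "msli_mdf"))
  i <- match(as.integer(d), block$dilations)
  if (is.na(i)) {
    stop("dilation ", d, " is not one of the block's factors (",
         paste(block$dilations, collapse = ", "), ")")
  }
  b <- as_batch(f)
  set_training(block, train)
  out <- with_no_grad({
    h <- forward(block$mods[[paste0("br", i, "_bn1")]],
                 forward(block$mods[[paste0("br", i, "_conv3")]], b$x))
    forward(block$mods[[paste0("br", i, "_bn2")]],
            forward(block$mods[[paste0("br", i, "_conv1")]], h))
  })
  unbatch(tg_value(out), b$squeeze)
}

#' Full MDF forward pass on a plain array
#'
#' @param block an [mdf_block()]
#' @param x array `(H, W, C)` or `(H, W, C, N)`
#' @param train logical
#' @return array of the same shape as `x`
#' @export
mdf_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "msli_mdf"))
  run_module(block, x, train)
}
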