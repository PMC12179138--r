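# ResNet50-style backbone: 7x7/2 stem with 3x3/2 max pooling, then four
# stages of bottleneck blocks ([3, 4, 6, 3]). Stage outputs c2..c5 sit at
# strides 4/8/16/32 with channels 256/512/1024/2048, scaled by the width
# multiplier (rounded to even counts so downstream channel splits stay
# exact).

even_channels <- function(base, wm) max(2L, 2L * as.integer(round(base * wm / 2)))

bottleneck_block <- function(in_channels, width, out_channels, stride = 1L) {
  m <- new_module("msli_bottleneck")
  m$mods$conv1 <- nn_conv2d(in_channels, width, 1L, bias = FALSE)
  m$mods$bn1 <- nn_batchnorm2d(width)
  m$mods$conv2 <- nn_conv2d(width, width, 3L, stride = stride, pad_h = 1L,
                            bias = FALSE)
  m$mods$bn2 <- nn_batchnorm2d(width)
  m$mods$conv3 <- nn_conv2d(width, out_channels, 1L, bias = FALSE)
  m$mods$bn3 <- nn_batchnorm2d(out_channels)
  m$project <- (stride != 1L || in_channels != out_channels)
  if (m$project) {
    m$mods$down_conv <- nn_conv2d(in_channels, out_channels, 1L,
                                  stride = stride, bias = FALSE)
    m$mods$down_bn <- nn_batchnorm2d(out_channels)
  }
  m
}

#' @export
forward.msli_bottleneck <- function(module, x, ...) {
  h <- op_relu(forward(module$mods$bn1, forward(module$mods$conv1, x)))
  h <- op_relu(forward(module$mods$bn2, forward(module$mods$conv2, h)))
  h <- forward(module$mods$bn3, forward(module$mods$conv3, h))
  sc <- if (module$project) {
    forward(module$mods$down_bn, forward(module$mods$down_conv, x))
  } else {
    x
  }
  op_relu(op_add(h, sc))
}

resnet_stage <- function(in_channels, width, out_channels, n_blocks, stride) {
  m <- new_module("msli_stage")
  m$mods$b1 <- bottleneck_block(in_channels, width, out_channels, stride)
  for (i in seq_len(n_blocks - 1L)) {
    m$mods[[paste0("b", i + 1L)]] <-
      bottleneck_block(out_channels, width, out_channels, 1L)
  }
  m
}

#' @export
forward.msli_stage <- function(module, x, ...) {
  for (blk in module$mods) x <- forward(blk, x)
  x
}

resnet_backbone <- function(width_multiplier = 1) {
  m <- new_module("msli_backbone")
  wm <- width_multiplier
  stem <- even_channels(64, wm)
  widths <- vapply(c(64, 128, 256, 512), even_channels, integer(1), wm = wm)
  outs <- vapply(c(256, 512, 1024, 2048), even_channels, integer(1), wm = wm)
  m$stage_channels <- outs
  m$mods$stem_conv <- nn_conv2d(3L, stem, 7L, stride = 2L, pad_h = 3L,
                                bias = FALSE)
  m$mods$stem_bn <- nn_batchnorm2d(stem)
  blocks <- c(3L, 4L, 6L, 3L)
  strides <- c(1L, 2L, 2L, 2L)
  ins <- c(stem, outs[1:3])
  for (i in 1:4) {
    m$mods[[paste0("layer", i)]] <-
      resnet_stage(ins[i], widths[i], outs[i], blocks[i], strides[i])
  }
  m
}

#' @export
forward.msli_backbone <- function(module, x, ...) {
  h <- op_relu(forward(module$mods$stem_bn, forward(module$mods$stem_conv, x)))
  h <- op_maxpool(h, k = 3L, stride = 2L, pad = 1L)
  c2 <- forward(module$mods$layer1, h)
  c3 <- forward(module$mods$layer2, c2)
  c4 <- forward(module$mods$layer3, c3)
  c5 <- forward(module$mods$layer4, c4)
  list(c2 = c2, c3 = c3, c4 = c4, c5 = c5)
}
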