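# Multi-scale dilation fusion block

test_that("configuration is validated", {
  expect_error(mdf_block(7L), "even channel count")
  expect_error(mdf_block(8L, dilations = c(0L, 2L)), ">= 1")
  blk <- mdf_block(8L)
  expect_error(mdf_forward(blk, rand_map(6, 6, 4)), "C = 8")
})

test_that("compression halves channels, rectifies, and matches the direct oracle", {
  set.seed(101)
  blk <- mdf_block(6L)
  randomize_bn(blk)
  x <- rand_map(5, 3, 6)
  f <- compress_channels(blk, x)
  expect_equal(dim(f), c(5, 3, 3))
  expect_true(all(f >= 0))
  ref <- relu_ref(bn_ref(conv_layer_ref(array(x, c(5, 3, 6, 1)),
                                        blk$mods$compress_conv),
                         blk$mods$compress_bn))
  expect_lt(max(abs(f - ref[, , , 1])), 1e-5)

  zero_parameters(blk)
  z <- compress_channels(blk, array(0, c(4, 4, 8))[, , 1:6])
  expect_true(all(z == 0))
})

test_that("dilated branches cover extents 13/25/37 via impulse responses", {
  # a 3x3 kernel at dilation d has taps only at offsets {-d, 0, d}^2,
  # i.e. an effective extent of 2d + 1
  expect_equal(3 + (3 - 1) * (c(6, 12, 18) - 1), c(13, 25, 37))
  set.seed(102)
  blk <- mdf_block(2L)
  for (d in c(6L, 12L, 18L)) {
    f <- array(0, c(41, 41, 1))
    f[21, 21, 1] <- 1
    br <- dilated_branch(blk, f, d)
    expect_equal(dim(br), dim(f))
    nz <- which(abs(br[, , 1]) > 1e-12, arr.ind = TRUE)
    offs <- unique(c(nz[, 1] - 21, nz[, 2] - 21))
    expect_true(all(offs %in% c(-d, 0, d)))
    # direct sparse-kernel placement: response present at all 9 offsets
    expect_equal(nrow(unique(nz)), 9)
  }
  expect_error(dilated_branch(blk, rand_map(8, 8, 1), 5L), "not one of")
})

test_that("dilated branch matches the direct-convolution oracle", {
  set.seed(103)
  blk <- mdf_block(4L, dilations = c(6L, 12L, 18L))
  randomize_bn(blk)
  f <- rand_map(15, 15, 2, 2)
  for (i in 1:3) {
    d <- blk$dilations[i]
    got <- dilated_branch(blk, f, d)
    ref <- bn_ref(conv_layer_ref(f, blk$mods[[paste0("br", i, "_conv3")]]),
                  blk$mods[[paste0("br", i, "_bn1")]])
    ref <- bn_ref(conv_layer_ref(ref, blk$mods[[paste0("br", i, "_conv1")]]),
                  blk$mods[[paste0("br", i, "_bn2")]])
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("zero-branch identity holds exactly on non-negative input", {
  set.seed(104)
  blk <- mdf_block(8L)
  zero_parameters(blk)
  x <- abs(rand_map(14, 14, 8))
  expect_identical(mdf_forward(blk, array(x, c(14, 14, 8))),
                   array(x, c(14, 14, 8)))
})

test_that("full forward preserves shape and matches the composition oracle", {
  set.seed(105)
  blk <- mdf_block(4L)
  randomize_bn(blk)
  x <- rand_map(8, 8, 4, 2)
  y <- mdf_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_lt(max(abs(y - mdf_ref(blk, x))), 1e-5)

  # ablation flag: rectification before the residual addition
  blk2 <- mdf_block(4L, relu_position = "before_add")
  for (nm in names(blk$params)) blk2$params[[nm]]$v <- blk$params[[nm]]$v
  for (nm in names(blk$mods)) {
    for (pn in names(blk$mods[[nm]]$params)) {
      blk2$mods[[nm]]$params[[pn]]$v <- blk$mods[[nm]]$params[[pn]]$v
    }
    blk2$mods[[nm]]$buffers <- blk$mods[[nm]]$buffers
  }
  xm <- rand_map(8, 8, 4)
  x4 <- array(xm, c(8, 8, 4, 1))
  fq <- relu_ref(bn_ref(conv_layer_ref(x4, blk2$mods$compress_conv),
                        blk2$mods$compress_bn))
  fr <- relu_ref(
    bn_ref(conv_layer_ref(fq, blk2$mods$skip_conv), blk2$mods$skip_bn) +
      Reduce(`+`, lapply(1:3, function(i) {
        h <- bn_ref(conv_layer_ref(fq, blk2$mods[[paste0("br", i, "_conv3")]]),
                    blk2$mods[[paste0("br", i, "_bn1")]])
        bn_ref(conv_layer_ref(h, blk2$mods[[paste0("br", i, "_conv1")]]),
               blk2$mods[[paste0("br", i, "_bn2")]])
      })))
  inner <- bn_ref(conv_layer_ref(conv_layer_ref(fr, blk2$mods$pw_conv),
                                 blk2$mods$expand_conv), blk2$mods$out_bn)
  ref <- array(relu_ref(inner), c(8, 8, 4)) + xm
  expect_lt(max(abs(mdf_forward(blk2, xm) - ref)), 1e-5)
})

test_that("every parameter receives gradient from a scalar loss", {
  set.seed(106)
  blk <- mdf_block(4L)
  x <- rand_map(14, 14, 4, 2)
  set_training(blk, TRUE)
  out <- forward(blk, mslinet:::tg_const(x))
  loss <- mslinet:::tg_op(sum(mslinet:::tg_value(out)^2), list(out),
                          function(g) list(2 * g * mslinet:::tg_value(out)))
  mslinet:::tg_backward(loss)
  ps <- parameters(blk)
  has_grad <- vapply(ps, function(p) !is.null(p$grad) && any(p$grad != 0),
                     logical(1))
  expect_true(all(has_grad))

  # finite-difference spot check on three parameters
  set_training(blk, FALSE)
  loss_at <- function() sum(mdf_forward(blk, x, train = FALSE)^2)
  set_training(blk, TRUE)
  out <- forward(blk, mslinet:::tg_const(x))
  loss <- mslinet:::tg_op(sum(mslinet:::tg_value(out)^2), list(out),
                          function(g) list(2 * g * mslinet:::tg_value(out)))
  for (p in ps) p$grad <- NULL
  mslinet:::tg_backward(loss)
  grads <- lapply(ps, function(p) p$grad)
  # compare against central differences computed in *training* mode
  loss_train <- function() {
    set_training(blk, TRUE)
    sum(mdf_forward(blk, x, train = TRUE)^2)
  }
  eps <- 1e-5
  for (nm in c("compress_conv.weight", "br2_conv3.weight", "out_bn.beta")) {
    p <- ps[[nm]]
    i <- 3L
    old <- p$v[i]
    p$v[i] <- old + eps; f1 <- loss_train()
    p$v[i] <- old - eps; f2 <- loss_train()
    p$v[i] <- old
    fd <- (f1 - f2) / (2 * eps)
    expect_lt(abs(fd - grads[[nm]][i]) / max(1, abs(fd)), 1e-3)
  }
})
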