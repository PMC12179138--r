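# Tensor engine: convolution variants against the direct oracle, pooling,
# batch normalization, and reverse-mode gradients by finite differences.

test_that("convolution variants agree with the direct oracle", {
  set.seed(401)
  cases <- list(
    list(x = c(5, 7, 4, 2), k = c(3, 3), cin = 4, cout = 6, stride = 1,
         ph = 1, pw = 1, dil = 1, g = 1),                      # padded 3x3
    list(x = c(9, 8, 4, 1), k = c(3, 3), cin = 4, cout = 4, stride = 2,
         ph = 1, pw = 1, dil = 1, g = 1),                      # strided
    list(x = c(14, 14, 2, 2), k = c(3, 3), cin = 2, cout = 2, stride = 1,
         ph = 6, pw = 6, dil = 6, g = 1),                      # dilated
    list(x = c(6, 6, 4, 2), k = c(1, 5), cin = 4, cout = 4, stride = 1,
         ph = 0, pw = 2, dil = 1, g = 4),                      # strip depthwise
    list(x = c(8, 8, 6, 2), k = c(1, 1), cin = 6, cout = 4, stride = 1,
         ph = 0, pw = 0, dil = 1, g = 1),                      # pointwise
    list(x = c(10, 10, 3, 1), k = c(7, 7), cin = 3, cout = 4, stride = 2,
         ph = 3, pw = 3, dil = 1, g = 1)                       # stem-like
  )
  for (cs in cases) {
    conv <- nn_conv2d(cs$cin, cs$cout, cs$k[1], cs$k[2], stride = cs$stride,
                      pad_h = cs$ph, pad_w = cs$pw, dilation = cs$dil,
                      groups = cs$g)
    x <- rand_map(cs$x[1], cs$x[2], cs$x[3], cs$x[4])
    got <- mslinet:::tg_value(mslinet:::op_conv2d(
      x, conv$params$weight$v, conv$params$bias$v, stride = cs$stride,
      pad_h = cs$ph, pad_w = cs$pw, dilation = cs$dil, groups = cs$g))
    ref <- conv_layer_ref(x, conv)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("convolution gradients match central differences", {
  set.seed(402)
  for (cs in list(list(k = c(3, 3), g = 1, ph = 1, pw = 1),
                  list(k = c(1, 1), g = 1, ph = 0, pw = 0),
                  list(k = c(5, 1), g = 4, ph = 2, pw = 0))) {
    conv <- nn_conv2d(4L, 4L, cs$k[1], cs$k[2], pad_h = cs$ph, pad_w = cs$pw,
                      groups = cs$g)
    xv <- rand_map(6, 6, 4, 2)
    dy <- NULL
    run <- function() {
      y <- conv_layer_ref(xv, conv)
      if (is.null(dy)) dy <<- array(stats::rnorm(length(y)), dim(y))
      sum(y * dy)
    }
    run()
    xt <- mslinet:::tg_param(xv)
    out <- mslinet:::op_conv2d(xt, conv$params$weight, conv$params$bias,
                               stride = 1L, pad_h = cs$ph, pad_w = cs$pw,
                               dilation = 1L, groups = cs$g)
    loss <- mslinet:::tg_op(sum(mslinet:::tg_value(out) * dy), list(out),
                            function(g) list(g * dy))
    mslinet:::tg_backward(loss)
    eps <- 1e-6
    for (tgt in list(list(t = xt, set = function(i, v) xv[i] <<- v,
                          get = function(i) xv[i]),
                     list(t = conv$params$weight,
                          set = function(i, v) conv$params$weight$v[i] <<- v,
                          get = function(i) conv$params$weight$v[i]))) {
      for (i in sample(length(tgt$t$v), 3)) {
        old <- tgt$get(i)
        tgt$set(i, old + eps); f1 <- run()
        tgt$set(i, old - eps); f2 <- run()
        tgt$set(i, old)
        expect_lt(abs((f1 - f2) / (2 * eps) - tgt$t$grad[i]), 1e-6)
      }
    }
  }
})

test_that("batch normalization normalizes in training mode and tracks stats", {
  set.seed(403)
  bn <- nn_batchnorm2d(3L)
  x <- rand_map(5, 4, 3, 6) * 2 + 1
  set_training(bn, TRUE)
  y <- mslinet:::tg_value(forward(bn, mslinet:::tg_const(x)))
  for (c in 1:3) {
    expect_lt(abs(mean(y[, , c, ])), 1e-8)
    expect_lt(abs(stats::var(as.vector(y[, , c, ])) - 1), 1e-2)
  }
  # running buffers move toward the batch statistics
  expect_gt(bn$buffers$running_mean[1], 0)
  set_training(bn, FALSE)
  ye <- mslinet:::tg_value(forward(bn, mslinet:::tg_const(x)))
  expect_lt(max(abs(ye - bn_ref(x, bn))), 1e-12)
})

test_that("max and average pooling agree with direct definitions", {
  set.seed(404)
  x <- rand_map(7, 7, 3, 2)
  mp <- mslinet:::tg_value(mslinet:::op_maxpool(x, k = 3L, stride = 2L, pad = 1L))
  expect_equal(dim(mp), c(4, 4, 3, 2))
  expect_equal(mp[2, 2, 1, 1], max(x[2:4, 2:4, 1, 1]))
  expect_equal(mp[1, 1, 3, 2], max(x[1:2, 1:2, 3, 2]))
  ap <- mslinet:::tg_value(mslinet:::op_avgpool(x, k = 3L, stride = 1L, pad = 1L))
  expect_lt(max(abs(ap - avgpool_ref(x, 3))), 1e-12)
})

test_that("softmax cross-entropy and its gradient are correct", {
  set.seed(405)
  K <- 5L; N <- 7L
  logits <- matrix(stats::rnorm(K * N), K, N)
  labels <- sample(0:(K - 1), N, replace = TRUE)
  lt <- mslinet:::tg_param(logits)
  loss <- mslinet:::op_softmax_ce(lt, labels)
  p <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  ref <- -mean(log(p[cbind(labels + 1L, 1:N)]))
  expect_lt(abs(as.numeric(loss$v) - ref), 1e-12)
  mslinet:::tg_backward(loss)
  eps <- 1e-6
  for (i in sample(length(logits), 4)) {
    l1 <- logits; l1[i] <- l1[i] + eps
    l2 <- logits; l2[i] <- l2[i] - eps
    f <- function(l) {
      p <- apply(l, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
      -mean(log(p[cbind(labels + 1L, 1:N)]))
    }
    expect_lt(abs((f(l1) - f(l2)) / (2 * eps) - lt$grad[i]), 1e-8)
  }
})

test_that("inference mode records no tape", {
  set.seed(406)
  conv <- nn_conv2d(2L, 2L, 3L, pad_h = 1L)
  x <- rand_map(5, 5, 2, 1)
  out <- with_no_grad(forward(conv, mslinet:::tg_const(x)))
  expect_length(out$parents, 0)
  expect_false(out$rg)
})
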