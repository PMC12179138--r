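# Independent brute-force oracles. Everything here is written directly from
# the operator definitions (plain loops and formulas) and shares no code
# with the package's im2col/GEMM, depthwise or pointwise kernels.

# direct dense convolution, layout (H, W, C, N) / weights (kh, kw, Cg, Cout)
conv_ref <- function(x, w, b = NULL, stride = 1, ph = 0, pw = ph, dil = 1,
                     groups = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  Coutg <- Cout / groups
  Ho <- (H + 2 * ph - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pw - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% Coutg
    for (wo in 1:Wo) for (ho in 1:Ho) {
      s <- if (!is.null(b) && length(b)) b[co] else 0
      for (ci in 1:Cg) for (ikw in 1:kw) for (ikh in 1:kh) {
        hi <- (ho - 1) * stride - ph + (ikh - 1) * dil + 1
        wi <- (wo - 1) * stride - pw + (ikw - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          s <- s + x[hi, wi, g * Cg + ci, n] * w[ikh, ikw, ci, co]
        }
      }
      y[ho, wo, co, n] <- s
    }
  }
  y
}

# batch-norm in inference mode, straight from the affine definition
bn_ref <- function(x, bn) {
  g <- bn$params$gamma$v; b <- bn$params$beta$v
  rm <- bn$buffers$running_mean; rv <- bn$buffers$running_var
  y <- x
  for (c in seq_len(dim(x)[3])) {
    y[, , c, ] <- (x[, , c, ] - rm[c]) / sqrt(rv[c] + bn$eps) * g[c] + b[c]
  }
  y
}

conv_layer_ref <- function(x, conv) {
  conv_ref(x, conv$params$weight$v,
           if (is.null(conv$params$bias)) NULL else conv$params$bias$v,
           stride = conv$stride, ph = conv$pad_h, pw = conv$pad_w,
           dil = conv$dilation, groups = conv$groups)
}

relu_ref <- function(x) pmax(x, 0)
sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# squeeze-excite from the formula: gate = sigm(W2 relu(W1 gap(x) + b1) + b2)
se_ref <- function(x, se) {
  d <- dim(x)
  y <- x
  for (n in seq_len(d[4])) {
    s <- apply(x[, , , n, drop = FALSE], 3, mean)
    z <- relu_ref(se$mods$fc1$params$weight$v %*% s + se$mods$fc1$params$bias$v)
    gate <- sigmoid_ref(se$mods$fc2$params$weight$v %*% z +
                          se$mods$fc2$params$bias$v)
    for (c in seq_len(d[3])) y[, , c, n] <- x[, , c, n] * gate[c]
  }
  y
}

# one-level Haar analysis by direct 2x2 block filtering (stride 2)
dwt_ref <- function(x) {
  d <- dim(x)
  f <- list(LL = matrix(c(.5, .5, .5, .5), 2),
            LH = matrix(c(.5, .5, -.5, -.5), 2),   # column difference
            HL = matrix(c(.5, -.5, .5, -.5), 2),   # row difference
            HH = matrix(c(.5, -.5, -.5, .5), 2))
  out <- lapply(f, function(k) {
    y <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      for (j in seq_len(d[2] / 2)) for (i in seq_len(d[1] / 2)) {
        blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]
        y[i, j, c, n] <- sum(blk * k)
      }
    }
    y
  })
  out
}

# synthesis by distributing each coefficient back through the same filters
idwt_ref <- function(s) {
  d <- dim(s$LL)
  H <- 2 * d[1]; W <- 2 * d[2]
  f <- list(LL = matrix(c(.5, .5, .5, .5), 2),
            LH = matrix(c(.5, .5, -.5, -.5), 2),
            HL = matrix(c(.5, -.5, .5, -.5), 2),
            HH = matrix(c(.5, -.5, -.5, .5), 2))
  y <- array(0, c(H, W, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      acc <- matrix(0, 2, 2)
      for (b in names(f)) acc <- acc + s[[b]][i, j, c, n] * f[[b]]
      y[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n] <- acc
    }
  }
  y
}

# average pooling with the divisor counting only in-bounds taps
avgpool_ref <- function(x, k, stride = 1, pad = (k - 1) %/% 2) {
  d <- dim(x)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      hs <- ((ho - 1) * stride - pad + 1):((ho - 1) * stride - pad + k)
      ws <- ((wo - 1) * stride - pad + 1):((wo - 1) * stride - pad + k)
      hs <- hs[hs >= 1 & hs <= d[1]]
      ws <- ws[ws >= 1 & ws <= d[2]]
      y[ho, wo, c, n] <- mean(x[hs, ws, c, n])
    }
  }
  y
}

# full MDF composition from the block's own weights, via the oracles above
mdf_ref <- function(block, x) {
  m <- block$mods
  f <- relu_ref(bn_ref(conv_layer_ref(x, m$compress_conv), m$compress_bn))
  acc <- bn_ref(conv_layer_ref(f, m$skip_conv), m$skip_bn)
  for (i in seq_along(block$dilations)) {
    h <- bn_ref(conv_layer_ref(f, m[[paste0("br", i, "_conv3")]]),
                m[[paste0("br", i, "_bn1")]])
    h <- bn_ref(conv_layer_ref(h, m[[paste0("br", i, "_conv1")]]),
                m[[paste0("br", i, "_bn2")]])
    acc <- acc + h
  }
  fr <- relu_ref(acc)
  y <- bn_ref(conv_layer_ref(conv_layer_ref(fr, m$pw_conv), m$expand_conv),
              m$out_bn)
  relu_ref(y + x)
}

# full LLM composition: crop / SE / stitch / 1x1+BN per window, global branch
llm_ref <- function(block, q) {
  d <- dim(q)
  win <- segment_windows(d[1])
  acc <- array(0, d)
  for (i in 1:4) {
    rows <- (win$start_row[i] + 1):win$end_row[i]
    sub <- q[rows, , , , drop = FALSE]
    ref <- se_ref(sub, block$mods[[paste0("se", i)]])
    full <- q
    full[rows, , , ] <- ref
    acc <- acc + bn_ref(conv_layer_ref(full, block$mods[[paste0("conv", i)]]),
                        block$mods[[paste0("bn", i)]])
  }
  acc + bn_ref(conv_layer_ref(se_ref(q, block$mods$se5), block$mods$conv5),
               block$mods$bn5)
}

# MSA composition: depthwise 5x5, identity + paired-strip paths, 1x1 mix
msa_ref <- function(block, x) {
  base <- conv_layer_ref(x, block$mods$dw)
  acc <- base
  for (i in seq_along(block$strip_extents)) {
    p <- conv_layer_ref(conv_layer_ref(base, block$mods[[paste0("strip", i, "_h")]]),
                        block$mods[[paste0("strip", i, "_v")]])
    acc <- acc + p
  }
  conv_layer_ref(acc, block$mods$pw)
}

# full WSSA composition: DWT -> stack -> pool -> MSA -> sigmoid -> gate -> IDWT
wssa_ref <- function(block, x) {
  s <- dwt_ref(x)
  C <- dim(x)[3]
  stk <- array(0, c(dim(x)[1] / 2, dim(x)[2] / 2, 4 * C, dim(x)[4]))
  for (i in 1:4) stk[, , (i - 1) * C + seq_len(C), ] <- s[[i]]
  ia <- avgpool_ref(stk, block$avgpool)
  att <- msa_ref(block$mods$msa, ia)
  wq <- sigmoid_ref(att)
  gated <- s
  for (i in 1:4) {
    gated[[i]] <- s[[i]] * wq[, , (i - 1) * C + seq_len(C), , drop = FALSE]
  }
  idwt_ref(gated)
}

# randomize batch-norm buffers so inference-mode normalization is non-trivial
randomize_bn <- function(module) {
  if (inherits(module, "nn_batchnorm2d")) {
    module$buffers$running_mean <- stats::rnorm(module$channels, sd = 0.3)
    module$buffers$running_var <- stats::runif(module$channels, 0.5, 2)
  }
  for (m in module$mods) randomize_bn(m)
  invisible(module)
}

# (H, W, C) map when N is omitted; explicit batches keep the 4th axis
rand_map <- function(H, W, C, N) {
  if (missing(N)) return(array(stats::rnorm(H * W * C), c(H, W, C)))
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}

# per-class TP/FP/FN metrics computed with plain loops and means
metrics_ref <- function(y_true, y_pred, k) {
  acc <- mean(y_true == y_pred)
  prec <- sens <- f1 <- numeric(k)
  for (c in 0:(k - 1)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1] <- if (prec[c + 1] + sens[c + 1] > 0) {
      2 * prec[c + 1] * sens[c + 1] / (prec[c + 1] + sens[c + 1])
    } else 0
  }
  list(accuracy = acc, precision = mean(prec), sensitivity = mean(sens),
       f1 = mean(f1))
}
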