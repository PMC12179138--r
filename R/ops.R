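# Differentiable primitives. Every op takes tensors or plain arrays,
# computes the value eagerly, and (when tracking) records a backward
# closure on the tape. Array layout is (H, W, C, N) throughout.

op_add <- function(a, b) {
  av <- tg_value(a); bv <- tg_value(b)
  v <- av + bv
  if (!tracking(a, b)) return(tg_const(v))
  tg_op(v, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  v <- tg_value(a) - tg_value(b)
  if (!tracking(a, b)) return(tg_const(v))
  tg_op(v, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  av <- tg_value(a); bv <- tg_value(b)
  v <- av * bv
  if (!tracking(a, b)) return(tg_const(v))
  tg_op(v, list(a, b), function(g) list(g * bv, g * av))
}

op_scale <- function(a, s) {
  v <- tg_value(a) * s
  if (!tracking(a)) return(tg_const(v))
  tg_op(v, list(a), function(g) list(g * s))
}

op_relu <- function(a) {
  av <- tg_value(a)
  v <- cpp_relu_fwd(av)
  if (!tracking(a)) return(tg_const(v))
  tg_op(v, list(a), function(g) list(cpp_relu_bwd(av, g)))
}

op_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-tg_value(a)))
  if (!tracking(a)) return(tg_const(v))
  tg_op(v, list(a), function(g) list(g * v * (1 - v)))
}

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad_h = 0L, pad_w = pad_h,
                      dilation = 1L, groups = 1L) {
  xv <- tg_value(x); wv <- tg_value(w)
  bv <- if (is.null(b)) numeric(0) else tg_value(b)
  xd <- dim(xv); wd <- dim(wv)
  single <- .msli$single
  # one-filter-per-channel convolutions take the direct depthwise path;
  # 1x1 stride-1 convolutions are pure channel mixes and skip im2col
  depthwise <- groups == xd[3] && wd[3] == 1L && wd[4] == groups
  pointwise <- !depthwise && wd[1] == 1L && wd[2] == 1L && stride == 1L &&
    groups == 1L && pad_h == 0L && pad_w == 0L
  v <- if (depthwise) {
    cpp_dwconv_fwd(xv, xd, wv, wd, bv, as.integer(stride),
                   as.integer(pad_h), as.integer(pad_w), as.integer(dilation))
  } else if (pointwise) {
    cpp_conv1x1_fwd(xv, xd, wv, bv)
  } else {
    cpp_conv2d_fwd(xv, xd, wv, wd, bv, as.integer(stride),
                   as.integer(pad_h), as.integer(pad_w),
                   as.integer(dilation), as.integer(groups), single)
  }
  inputs <- if (is.null(b)) list(x, w) else list(x, w, b)
  if (!tracking(x, w, b)) return(tg_const(v))
  need_dx <- is_tensor(x) && x$rg
  has_bias <- !is.null(b)
  tg_op(v, inputs, function(g) {
    gr <- if (depthwise) {
      cpp_dwconv_bwd(xv, xd, wv, wd, g, as.integer(stride),
                     as.integer(pad_h), as.integer(pad_w),
                     as.integer(dilation), need_dx, has_bias)
    } else if (pointwise) {
      cpp_conv1x1_bwd(xv, xd, wv, g, need_dx, has_bias)
    } else {
      cpp_conv2d_bwd(xv, xd, wv, wd, g, as.integer(stride),
                     as.integer(pad_h), as.integer(pad_w),
                     as.integer(dilation), as.integer(groups),
                     need_dx, has_bias, single)
    }
    if (has_bias) list(if (need_dx) gr$dx else NULL, gr$dw, gr$db)
    else list(if (need_dx) gr$dx else NULL, gr$dw)
  })
}

op_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- tg_value(x)
  xd <- dim(xv)
  r <- cpp_maxpool_fwd(xv, xd, as.integer(k), as.integer(stride), as.integer(pad))
  if (!tracking(x)) return(tg_const(r$y))
  idx <- r$idx
  tg_op(r$y, list(x), function(g) list(cpp_maxpool_bwd(g, idx, xd)))
}

op_avgpool <- function(x, k = 3L, stride = 1L, pad = 1L) {
  xv <- tg_value(x)
  xd <- dim(xv)
  v <- cpp_avgpool_fwd(xv, xd, as.integer(k), as.integer(stride), as.integer(pad))
  if (!tracking(x)) return(tg_const(v))
  tg_op(v, list(x), function(g)
    list(cpp_avgpool_bwd(g, xd, as.integer(k), as.integer(stride), as.integer(pad))))
}

# Global average pooling: (H, W, C, N) -> (C, N).
op_gap <- function(x) {
  xv <- tg_value(x)
  d <- dim(xv)
  S <- d[1] * d[2]
  v <- matrix(colMeans(matrix(xv, nrow = S)), nrow = d[3], ncol = d[4])
  if (!tracking(x)) return(tg_const(v))
  tg_op(v, list(x), function(g) {
    dx <- array(rep(as.vector(g) / S, each = S), dim = d)
    list(dx)
  })
}

# Per-channel, per-sample scaling: x (H,W,C,N) * gate (C,N).
op_channel_scale <- function(x, gate) {
  xv <- tg_value(x); gv <- tg_value(gate)
  d <- dim(xv)
  S <- d[1] * d[2]
  gfull <- rep(as.vector(gv), each = S)
  v <- array(as.vector(xv) * gfull, dim = d)
  if (!tracking(x, gate)) return(tg_const(v))
  tg_op(v, list(x, gate), function(g) {
    dx <- array(as.vector(g) * gfull, dim = d)
    dgate <- matrix(colSums(matrix(as.vector(g) * as.vector(xv), nrow = S)),
                    nrow = d[3], ncol = d[4])
    list(dx, dgate)
  })
}

# Dense layer on feature-vector batches: x (F, N), W (out, F), b (out).
op_linear <- function(x, w, b) {
  xv <- tg_value(x); wv <- tg_value(w); bv <- tg_value(b)
  v <- wv %*% xv + bv
  if (!tracking(x, w, b)) return(tg_const(v))
  tg_op(v, list(x, w, b), function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

op_concat_channels <- function(xs) {
  vs <- lapply(xs, tg_value)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  v <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (i in seq_along(vs)) {
    v[, , off + seq_len(cs[i]), ] <- vs[[i]]
    off <- off + cs[i]
  }
  if (!do.call(tracking, xs)) return(tg_const(v))
  tg_op(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

op_channel_slice <- function(x, idx) {
  xv <- tg_value(x)
  d <- dim(xv)
  v <- xv[, , idx, , drop = FALSE]
  if (!tracking(x)) return(tg_const(v))
  tg_op(v, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

# Row window extraction (1-based inclusive row indices).
op_rows_crop <- function(x, rows) {
  xv <- tg_value(x)
  d <- dim(xv)
  v <- xv[rows, , , , drop = FALSE]
  if (!tracking(x)) return(tg_const(v))
  tg_op(v, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[rows, , , ] <- g
    list(dx)
  })
}

# Re-stitch: rows `rows` of q are replaced by `r`; all other rows kept from q.
op_rows_stitch <- function(q, r, rows) {
  qv <- tg_value(q); rv <- tg_value(r)
  v <- qv
  v[rows, , , ] <- rv
  if (!tracking(q, r)) return(tg_const(v))
  tg_op(v, list(q, r), function(g) {
    dq <- g
    dq[rows, , , ] <- 0
    list(dq, g[rows, , , , drop = FALSE])
  })
}

# --- Orthonormal Haar analysis/synthesis -------------------------------------
#
# Subband order is fixed as (LL, LH, HL, HH). With array layout (H, W, ...):
# LH is the horizontal-detail band (responds to oscillation across the width
# axis), HL the vertical-detail band. Filters have entries +-1/2, so the
# transform is orthonormal: energy is conserved and synthesis is the exact
# transpose/inverse of analysis.

haar_stack_fwd <- function(xv) {
  d <- dim(xv)
  H <- d[1]; W <- d[2]
  oh <- seq(1L, H, 2L); eh <- seq(2L, H, 2L)
  ow <- seq(1L, W, 2L); ew <- seq(2L, W, 2L)
  a <- xv[oh, ow, , , drop = FALSE]
  b <- xv[oh, ew, , , drop = FALSE]
  cc <- xv[eh, ow, , , drop = FALSE]
  dd <- xv[eh, ew, , , drop = FALSE]
  C <- d[3]
  v <- array(0, dim = c(H / 2, W / 2, 4L * C, d[4]))
  v[, , seq_len(C), ] <- (a + b + cc + dd) / 2
  v[, , C + seq_len(C), ] <- (a - b + cc - dd) / 2
  v[, , 2L * C + seq_len(C), ] <- (a + b - cc - dd) / 2
  v[, , 3L * C + seq_len(C), ] <- (a - b - cc + dd) / 2
  v
}

haar_stack_inv <- function(sv) {
  d <- dim(sv)
  C <- d[3] / 4L
  i1 <- seq_len(C)
  LL <- sv[, , i1, , drop = FALSE]
  LH <- sv[, , C + i1, , drop = FALSE]
  HL <- sv[, , 2L * C + i1, , drop = FALSE]
  HH <- sv[, , 3L * C + i1, , drop = FALSE]
  H <- 2L * d[1]; W <- 2L * d[2]
  y <- array(0, dim = c(H, W, C, d[4]))
  oh <- seq(1L, H, 2L); eh <- seq(2L, H, 2L)
  ow <- seq(1L, W, 2L); ew <- seq(2L, W, 2L)
  y[oh, ow, , ] <- (LL + LH + HL + HH) / 2
  y[oh, ew, , ] <- (LL - LH + HL - HH) / 2
  y[eh, ow, , ] <- (LL + LH - HL - HH) / 2
  y[eh, ew, , ] <- (LL - LH - HL + HH) / 2
  y
}

op_dwt_stack <- function(x) {
  xv <- tg_value(x)
  d <- dim(xv)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("Haar analysis requires even spatial size, got ", d[1], "x", d[2])
  }
  v <- haar_stack_fwd(xv)
  if (!tracking(x)) return(tg_const(v))
  # orthonormal linear map: the adjoint of analysis is synthesis
  tg_op(v, list(x), function(g) list(haar_stack_inv(g)))
}

op_idwt_stack <- function(s) {
  sv <- tg_value(s)
  v <- haar_stack_inv(sv)
  if (!tracking(s)) return(tg_const(v))
  tg_op(v, list(s), function(g) list(haar_stack_fwd(g)))
}

# Softmax cross-entropy over logits (K, N) against 0-based integer labels.
op_softmax_ce <- function(logits, labels) {
  lv <- tg_value(logits)
  K <- nrow(lv); N <- ncol(lv)
  m <- apply(lv, 2, max)
  z <- exp(sweep(lv, 2, m))
  p <- sweep(z, 2, colSums(z), "/")
  li <- cbind(as.integer(labels) + 1L, seq_len(N))
  idx <- li[, 1] + K * (li[, 2] - 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  if (!tracking(logits)) {
    out <- tg_const(loss)
    out$probs <- p
    return(out)
  }
  node <- tg_op(loss, list(logits), function(g) {
    dp <- p
    dp[idx] <- dp[idx] - 1
    list(dp * (as.numeric(g) / N))
  })
  node$probs <- p
  node
}

# Concatenate feature-vector batches (F_i, N) along the feature axis.
op_concat_rows <- function(xs) {
  vs <- lapply(xs, tg_value)
  v <- do.call(rbind, vs)
  if (!do.call(tracking, xs)) return(tg_const(v))
  ns <- vapply(vs, nrow, numeric(1))
  tg_op(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[off + seq_len(ns[i]), , drop = FALSE]
      off <- off + ns[i]
    }
    out
  })
}
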