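# Wavelet subband spatial attention (WSSA).
#
# One level of orthonormal Haar analysis splits the map into LL/LH/HL/HH
# subbands at half resolution. The four subbands are stacked along channels
# (4C), smoothed by a shape-preserving average pooling, passed through a
# convolutional multi-scale attention core (5x5 depthwise convolution, four
# parallel feed-forward paths — identity plus three paired-strip depthwise
# paths — summed, then 1x1 convolution), squashed by a sigmoid into gates in
# (0, 1), split back into four C-channel weight maps, multiplied against the
# ORIGINAL subbands, and reconstructed by Haar synthesis. With all gates at
# 1 the block is the identity; with all gates at 0 it annihilates the input.

#' One-level orthonormal Haar analysis
#'
#' Filters have entries plus/minus 1/2 on 2x2 blocks at stride 2, so the
#' transform conserves energy and [haar_idwt2()] inverts it exactly. With
#' array layout `(H, W, C)`, `LH` is the horizontal-detail band (responds to
#' oscillation across the width axis) and `HL` the vertical-detail band.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)` with even `H` and `W`
#' @return named list of subbands `LL`, `LH`, `HL`, `HH`, each at half the
#'   spatial size of `x`
#' @export
haar_dwt2 <- function(x) {
  b <- as_batch(x)
  xv <- tg_value(b$x)
  d <- dim(xv)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("Haar analysis requires even spatial size, got ", d[1], "x", d[2])
  }
  s <- haar_stack_fwd(xv)
  C <- d[3]
  out <- list(
    LL = s[, , seq_len(C), , drop = FALSE],
    LH = s[, , C + seq_len(C), , drop = FALSE],
    HL = s[, , 2L * C + seq_len(C), , drop = FALSE],
    HH = s[, , 3L * C + seq_len(C), , drop = FALSE]
  )
  lapply(out, unbatch, squeeze = b$squeeze)
}

#' One-level orthonormal Haar synthesis
#'
#' Exact inverse of [haar_dwt2()].
#'
#' @param s named list with subbands `LL`, `LH`, `HL`, `HH` of identical shape
#' @return array of twice the spatial size of the subbands
#' @export
haar_idwt2 <- function(s) {
  stopifnot(all(c("LL", "LH", "HL", "HH") %in% names(s)))
  parts <- lapply(s[c("LL", "LH", "HL", "HH")], function(p) as_batch(p))
  dims <- lapply(parts, function(p) dim(tg_value(p$x)))
  if (length(unique(lapply(dims, identity))) != 1L) {
    stop("subbands must share an identical shape; got ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
               collapse = ", "))
  }
  d <- dims[[1]]
  stk <- array(0, dim = c(d[1], d[2], 4L * d[3], d[4]))
  for (i in 1:4) stk[, , (i - 1L) * d[3] + seq_len(d[3]), ] <- tg_value(parts[[i]]$x)
  unbatch(haar_stack_inv(stk), parts[[1]]$squeeze)
}

#' Convolutional multi-scale attention core
#'
#' A 5x5 depthwise convolution followed by four parallel feed-forward paths
#' (identity plus one paired strip path — `1 x k` then `k x 1` depthwise —
#' per entry of `strip_extents`), summed and mixed by a 1x1 convolution.
#' Shape preserving.
#'
#' @param channels channel count the core operates at
#' @param dw_kernel extent of the leading depthwise convolution
#' @param strip_extents extents of the paired strip paths
#' @return an MSA module usable with [forward()] / [msa_forward()]
#' @export
msa_block <- function(channels, dw_kernel = 5L, strip_extents = c(7L, 11L, 21L)) {
  m <- new_module("msli_msa")
  m$channels <- as.integer(channels)
  m$strip_extents <- as.integer(strip_extents)
  p <- (dw_kernel - 1L) %/% 2L
  m$mods$dw <- nn_conv2d(channels, channels, dw_kernel, pad_h = p,
                         groups = channels)
  for (i in seq_along(strip_extents)) {
    k <- as.integer(strip_extents[i])
    m$mods[[paste0("strip", i, "_h")]] <-
      nn_conv2d(channels, channels, 1L, k, pad_h = 0L, pad_w = (k - 1L) %/% 2L,
                groups = channels)
    m$mods[[paste0("strip", i, "_v")]] <-
      nn_conv2d(channels, channels, k, 1L, pad_h = (k - 1L) %/% 2L, pad_w = 0L,
                groups = channels)
  }
  m$mods$pw <- nn_conv2d(channels, channels, 1L)
  m
}

#' @export
forward.msli_msa <- function(module, x, ...) {
  xv <- tg_value(x)
  if (dim(xv)[3] != module$channels) {
    stop("MSA configured for ", module$channels, " channels, input has ",
         dim(xv)[3])
  }
  base <- forward(module$mods$dw, x)
  acc <- base  # identity feed-forward path
  for (i in seq_along(module$strip_extents)) {
    p <- forward(module$mods[[paste0("strip", i, "_v")]],
                 forward(module$mods[[paste0("strip", i, "_h")]], base))
    acc <- op_add(acc, p)
  }
  forward(module$mods$pw, acc)
}

#' MSA forward pass on a plain array
#'
#' @param block an [msa_block()]
#' @param x array `(H, W, C)` or `(H, W, C, N)`
#' @param train logical
#' @return array of the same shape as `x`
#' @export
msa_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "msli_msa"))
  run_module(block, x, train)
}

SUBBAND_NAMES <- c("LL", "LH", "HL", "HH")

#' Wavelet subband spatial attention block
#'
#' @param channels input channel count `C`; the attention core operates on
#'   the stacked subbands (`4C`, or `3C` when one subband is excluded)
#' @param avgpool extent of the shape-preserving average pooling applied to
#'   the stacked subbands (stride 1, padding `(k-1)/2`)
#' @param strip_extents strip extents of the attention core
#' @param drop_subband `"none"` or one of `"LL"`, `"LH"`, `"HL"`, `"HH"`:
#'   the named subband bypasses attention unweighted and only the remaining
#'   three are stacked and processed (subband-dropping ablation)
#' @param mode `"wssa"` (full block), `"owt"` (plain analysis/synthesis
#'   round trip, no parameters) or `"per_subband_msa"` (an independent
#'   attention core per subband, no gating) — the two comparison wirings
#' @return a WSSA module usable with [forward()] / [wssa_forward()]. The
#'   field `gate_override` (NULL, 0 or 1) forces all attention gates to a
#'   constant.
#' @export
wssa_block <- function(channels, avgpool = 3L, strip_extents = c(7L, 11L, 21L),
                       drop_subband = "none",
                       mode = c("wssa", "owt", "per_subband_msa")) {
  mode <- match.arg(mode)
  if (!drop_subband %in% c("none", SUBBAND_NAMES)) {
    stop("drop_subband must be 'none' or one of LL/LH/HL/HH")
  }
  m <- new_module("msli_wssa")
  m$channels <- as.integer(channels)
  m$avgpool <- as.integer(avgpool)
  m$drop_subband <- drop_subband
  m$mode <- mode
  m$gate_override <- NULL
  if (mode == "wssa") {
    n_att <- if (drop_subband == "none") 4L else 3L
    m$mods$msa <- msa_block(n_att * channels, strip_extents = strip_extents)
  } else if (mode == "per_subband_msa") {
    for (b in SUBBAND_NAMES) {
      m$mods[[paste0("msa_", b)]] <- msa_block(channels,
                                               strip_extents = strip_extents)
    }
  }
  m
}

#' @export
forward.msli_wssa <- function(module, x, ...) {
  xv <- tg_value(x)
  d <- dim(xv)
  if (d[3] != module$channels) {
    stop("WSSA configured for C = ", module$channels, ", input has ", d[3])
  }
  s <- op_dwt_stack(x)  # errors on odd spatial size
  C <- module$channels
  if (module$mode == "owt") return(op_idwt_stack(s))
  if (module$mode == "per_subband_msa") {
    parts <- vector("list", 4L)
    for (i in 1:4) {
      sub <- op_channel_slice(s, (i - 1L) * C + seq_len(C))
      parts[[i]] <- forward(module$mods[[paste0("msa_", SUBBAND_NAMES[i])]], sub)
    }
    return(op_idwt_stack(op_concat_channels(parts)))
  }
  kept <- if (module$drop_subband == "none") 1:4 else
    which(SUBBAND_NAMES != module$drop_subband)
  kept_idx <- as.vector(vapply(kept, function(i) (i - 1L) * C + seq_len(C),
                               integer(C)))
  sel <- if (length(kept) == 4L) s else op_channel_slice(s, kept_idx)
  if (!is.null(module$gate_override)) {
    sd <- dim(tg_value(sel))
    gates <- tg_const(array(module$gate_override, dim = sd))
  } else {
    ia <- op_avgpool(sel, k = module$avgpool, stride = 1L,
                     pad = (module$avgpool - 1L) %/% 2L)
    gates <- op_sigmoid(forward(module$mods$msa, ia))
  }
  gated <- op_mul(sel, gates)
  if (length(kept) == 4L) {
    return(op_idwt_stack(gated))
  }
  # excluded subband passes to synthesis unmodified
  parts <- vector("list", 4L)
  for (i in 1:4) {
    pos <- match(i, kept)
    parts[[i]] <- if (is.na(pos)) {
      op_channel_slice(s, (i - 1L) * C + seq_len(C))
    } else {
      op_channel_slice(gated, (pos - 1L) * C + seq_len(C))
    }
  }
  op_idwt_stack(op_concat_channels(parts))
}

#' WSSA forward pass on a plain array
#'
#' @param block a [wssa_block()]
#' @param x array `(H, W, C)` or `(H, W, C, N)` with even spatial size
#' @param train logical
#' @return array of the same shape as `x`
#' @export
wssa_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "msli_wssa"))
  run_module(block, x, train)
}
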