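# Elementary layers: convolution, batch normalization, dense, and
# squeeze-and-excitation channel attention.

#' 2-D convolution layer
#'
#' Weights use Kaiming fan-in initialization, `sd = sqrt(2 / fan_in)`;
#' biases (when present) start at zero. Convolutions that are immediately
#' followed by batch normalization are constructed without bias.
#'
#' @param in_channels,out_channels channel counts
#' @param kh,kw kernel extent along rows/columns
#' @param stride stride (both axes)
#' @param pad_h,pad_w zero padding along rows/columns
#' @param dilation tap spacing; a `k` x `k` kernel at dilation `d` covers an
#'   extent of `k + (k - 1) (d - 1)` pixels
#' @param groups grouped convolution (`groups = in_channels` is depthwise)
#' @param bias logical
#' @return a conv2d module
#' @export
nn_conv2d <- function(in_channels, out_channels, kh, kw = kh, stride = 1L,
                      pad_h = 0L, pad_w = pad_h, dilation = 1L, groups = 1L,
                      bias = TRUE) {
  if (in_channels %% groups != 0L || out_channels %% groups != 0L) {
    stop("channels (", in_channels, " -> ", out_channels,
         ") not divisible by groups (", groups, ")")
  }
  m <- new_module("nn_conv2d")
  m$in_channels <- as.integer(in_channels)
  m$out_channels <- as.integer(out_channels)
  m$kh <- as.integer(kh); m$kw <- as.integer(kw)
  m$stride <- as.integer(stride)
  m$pad_h <- as.integer(pad_h); m$pad_w <- as.integer(pad_w)
  m$dilation <- as.integer(dilation)
  m$groups <- as.integer(groups)
  fan_in <- kh * kw * in_channels / groups
  m$params$weight <- tg_param(array(
    stats::rnorm(kh * kw * (in_channels / groups) * out_channels,
                 sd = sqrt(2 / fan_in)),
    dim = c(kh, kw, in_channels / groups, out_channels)))
  if (bias) m$params$bias <- tg_param(numeric(out_channels))
  m
}

#' @export
forward.nn_conv2d <- function(module, x, ...) {
  op_conv2d(x, module$params$weight, module$params$bias,
            stride = module$stride, pad_h = module$pad_h, pad_w = module$pad_w,
            dilation = module$dilation, groups = module$groups)
}

# Set a 1x1 convolution to the exact identity map (requires C_in == C_out).
set_conv_identity <- function(conv) {
  stopifnot(conv$kh == 1L, conv$kw == 1L, conv$in_channels == conv$out_channels,
            conv$groups == 1L)
  C <- conv$in_channels
  conv$params$weight$v <- array(diag(C), dim = c(1L, 1L, C, C))
  if (!is.null(conv$params$bias)) conv$params$bias$v <- numeric(C)
  invisible(conv)
}

#' Batch normalization over the spatial and batch axes
#'
#' Per-channel standardization with learned scale/offset. In training mode
#' batch statistics are used and exponentially averaged into running
#' buffers; in inference mode the running buffers are used.
#'
#' @param channels channel count
#' @param eps numerical floor added to the variance
#' @param momentum running-average update weight
#' @return a batch-norm module
#' @export
nn_batchnorm2d <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- new_module("nn_batchnorm2d")
  m$channels <- as.integer(channels)
  m$eps <- eps
  m$momentum <- momentum
  m$params$gamma <- tg_param(rep(1, channels))
  m$params$beta <- tg_param(numeric(channels))
  m$buffers$running_mean <- numeric(channels)
  m$buffers$running_var <- rep(1, channels)
  m
}

#' @export
forward.nn_batchnorm2d <- function(module, x, ...) {
  xv <- tg_value(x)
  xd <- dim(xv)
  training <- isTRUE(module$training)
  if (training) {
    st <- cpp_bn_stats(xv, xd)
    mean <- st$mean; var <- st$var
    mom <- module$momentum
    module$buffers$running_mean <- (1 - mom) * module$buffers$running_mean + mom * mean
    module$buffers$running_var <- (1 - mom) * module$buffers$running_var + mom * var
  } else {
    mean <- module$buffers$running_mean
    var <- module$buffers$running_var
  }
  invstd <- 1 / sqrt(var + module$eps)
  gamma <- module$params$gamma
  beta <- module$params$beta
  v <- cpp_bn_fwd(xv, xd, gamma$v, beta$v, mean, invstd)
  if (!tracking(x, gamma, beta)) return(tg_const(v))
  gv <- gamma$v
  tg_op(v, list(x, gamma, beta), function(g) {
    gr <- cpp_bn_bwd(xv, xd, g, gv, mean, invstd, training)
    list(gr$dx, gr$dgamma, gr$dbeta)
  })
}

# Make a batch-norm layer an exact identity in inference mode: running
# variance is set to 1 - eps so that 1/sqrt(var + eps) == 1 exactly.
set_bn_identity <- function(bn) {
  bn$params$gamma$v <- rep(1, bn$channels)
  bn$params$beta$v <- numeric(bn$channels)
  bn$buffers$running_mean <- numeric(bn$channels)
  bn$buffers$running_var <- rep(1 - bn$eps, bn$channels)
  invisible(bn)
}

#' Dense (fully connected) layer
#'
#' @param in_features,out_features feature counts
#' @param init_sd weight initialization scale; defaults to Kaiming fan-in
#' @return a linear module
#' @export
nn_linear <- function(in_features, out_features,
                      init_sd = sqrt(2 / in_features)) {
  m <- new_module("nn_linear")
  m$in_features <- as.integer(in_features)
  m$out_features <- as.integer(out_features)
  m$params$weight <- tg_param(matrix(
    stats::rnorm(out_features * in_features, sd = init_sd),
    nrow = out_features))
  m$params$bias <- tg_param(numeric(out_features))
  m
}

#' @export
forward.nn_linear <- function(module, x, ...) {
  op_linear(x, module$params$weight, module$params$bias)
}

#' Squeeze-and-excitation channel attention
#'
#' Global average pooling to a channel descriptor, a bottleneck
#' (`C -> C/r -> C`) with rectification, a sigmoid gate in (0, 1), and
#' channelwise rescaling of the input.
#'
#' @param channels channel count `C`
#' @param reduction bottleneck ratio `r`; must satisfy `C >= r`
#' @return an SE module. The field `gate_override` (NULL, 0 or 1) forces all
#'   gates to a constant, used by the block-identity tests.
#' @export
nn_se <- function(channels, reduction = 16L) {
  if (channels < reduction) {
    stop("SE block needs channels >= reduction, got C=", channels,
         ", r=", reduction)
  }
  m <- new_module("nn_se")
  m$channels <- as.integer(channels)
  m$reduction <- as.integer(reduction)
  hidden <- max(1L, as.integer(channels %/% reduction))
  m$mods$fc1 <- nn_linear(channels, hidden)
  m$mods$fc2 <- nn_linear(hidden, channels)
  m$gate_override <- NULL
  m
}

#' @export
forward.nn_se <- function(module, x, ...) {
  xv <- tg_value(x)
  d <- dim(xv)
  if (!is.null(module$gate_override)) {
    gate <- tg_const(matrix(module$gate_override, nrow = d[3], ncol = d[4]))
    return(op_channel_scale(x, gate))
  }
  s <- op_gap(x)
  z <- op_relu(forward(module$mods$fc1, s))
  gate <- op_sigmoid(forward(module$mods$fc2, z))
  op_channel_scale(x, gate)
}
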