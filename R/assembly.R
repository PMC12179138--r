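# Full network assembly: backbone stages -> per-stage MDF -> reduced
# feature-pyramid laterals (1x1 projections only; no top-down pathway, no
# upsampling, no cross-scale addition) -> per-branch LLM -> WSSA on the
# first three branches (the 7x7 deepest branch is odd-sized and bypasses the
# wavelet block) -> global average pooling -> channel concatenation -> one
# linear classifier.

#' Model configuration
#'
#' @param n_classes number of output classes
#' @param fpn_width lateral projection width at unit width multiplier
#' @param use_mdf,use_llm,use_wssa enable the three blocks (ablation wiring)
#' @param width_multiplier channel scaling in (0, 1] for desk-scale models;
#'   all widths (backbone, laterals) are scaled and rounded to even counts
#' @param pretrained_backbone must be `FALSE`: no pretrained weights are
#'   bundled; the backbone is randomly initialized
#' @param input_size square input extent; must be divisible by 32 with
#'   `input_size / 32 >= 7` so every branch satisfies the row-split
#'   precondition (224 is the reference value)
#' @param dilations MDF dilation factors
#' @param se_reduction LLM squeeze-and-excitation bottleneck ratio
#' @param wssa_avgpool,wssa_strip_extents,wssa_drop_subband,wssa_mode passed
#'   to [wssa_block()]
#' @param mdf_relu_position passed to [mdf_block()]
#' @return a config list of class `msli_config`
#' @export
msli_config <- function(n_classes = 8L, fpn_width = 256L,
                        use_mdf = TRUE, use_llm = TRUE, use_wssa = TRUE,
                        width_multiplier = 1, pretrained_backbone = FALSE,
                        input_size = 224L, dilations = c(6L, 12L, 18L),
                        se_reduction = 16L, wssa_avgpool = 3L,
                        wssa_strip_extents = c(7L, 11L, 21L),
                        wssa_drop_subband = "none",
                        wssa_mode = "wssa",
                        mdf_relu_position = "after_add") {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L || input_size %/% 32L < 7L) {
    stop("input_size must be divisible by 32 with input_size/32 >= 7 ",
         "(the deepest branch must still split into 7 row segments); ",
         "got ", input_size)
  }
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop("width_multiplier must lie in (0, 1]")
  }
  if (isTRUE(pretrained_backbone)) {
    stop("no pretrained backbone weights are bundled with this package; ",
         "use pretrained_backbone = FALSE")
  }
  cfg <- list(
    n_classes = as.integer(n_classes), fpn_width = as.integer(fpn_width),
    use_mdf = isTRUE(use_mdf), use_llm = isTRUE(use_llm),
    use_wssa = isTRUE(use_wssa), width_multiplier = width_multiplier,
    pretrained_backbone = FALSE, input_size = input_size,
    dilations = as.integer(dilations), se_reduction = as.integer(se_reduction),
    wssa_avgpool = as.integer(wssa_avgpool),
    wssa_strip_extents = as.integer(wssa_strip_extents),
    wssa_drop_subband = wssa_drop_subband, wssa_mode = wssa_mode,
    mdf_relu_position = mdf_relu_position
  )
  class(cfg) <- "msli_config"
  cfg
}

#' Ablation wirings
#'
#' Named block combinations: `"baseline"` (backbone + laterals + pooled
#' concat classifier), `"mdf"`, `"mdf+llm"`, `"llm+wssa"`, `"mdf+wssa"`,
#' and `"full"`.
#'
#' @param name wiring name
#' @param ... further arguments passed to [msli_config()]
#' @return an `msli_config`
#' @export
ablation_config <- function(name = c("baseline", "mdf", "mdf+llm", "llm+wssa",
                                     "mdf+wssa", "full"), ...) {
  name <- match.arg(name)
  flags <- switch(name,
    "baseline" = c(FALSE, FALSE, FALSE),
    "mdf" = c(TRUE, FALSE, FALSE),
    "mdf+llm" = c(TRUE, TRUE, FALSE),
    "llm+wssa" = c(FALSE, TRUE, TRUE),
    "mdf+wssa" = c(TRUE, FALSE, TRUE),
    "full" = c(TRUE, TRUE, TRUE)
  )
  msli_config(use_mdf = flags[1], use_llm = flags[2], use_wssa = flags[3], ...)
}

#' Build the full classification network
#'
#' @param config an [msli_config()]
#' @return a network module. `forward()` consumes `(H, W, 3, N)` arrays and
#'   returns `(n_classes, N)` logits; see [msli_forward()] for the
#'   plain-array interface.
#' @export
msli_net <- function(config = msli_config()) {
  stopifnot(inherits(config, "msli_config"))
  net <- new_module("msli_net")
  net$config <- config
  wm <- config$width_multiplier
  net$mods$backbone <- resnet_backbone(wm)
  sc <- net$mods$backbone$stage_channels
  fw <- even_channels(config$fpn_width, wm)
  net$fpn_width <- fw
  if (config$use_mdf) {
    for (i in 1:4) {
      net$mods[[paste0("mdf", i)]] <-
        mdf_block(sc[i], dilations = config$dilations,
                  relu_position = config$mdf_relu_position)
    }
  }
  for (i in 1:4) {
    net$mods[[paste0("lateral", i)]] <- nn_conv2d(sc[i], fw, 1L)
  }
  if (config$use_llm) {
    for (i in 1:4) {
      net$mods[[paste0("llm", i)]] <-
        llm_block(fw, se_reduction = config$se_reduction)
    }
  }
  if (config$use_wssa) {
    for (i in 1:3) {
      net$mods[[paste0("wssa", i)]] <-
        wssa_block(fw, avgpool = config$wssa_avgpool,
                   strip_extents = config$wssa_strip_extents,
                   drop_subband = config$wssa_drop_subband,
                   mode = config$wssa_mode)
    }
  }
  net$mods$classifier <- nn_linear(4L * fw, config$n_classes, init_sd = 0.01)
  net$stats <- list(wssa_calls = 0L)
  net
}

#' @export
forward.msli_net <- function(module, x, ...) {
  cfg <- module$config
  xv <- tg_value(x)
  d <- dim(xv)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 3L) {
    stop("expected input of shape (", cfg$input_size, ", ", cfg$input_size,
         ", 3, N); got (", paste(d, collapse = ", "), ")")
  }
  stages <- forward(module$mods$backbone, x)
  module$stats$wssa_calls <- 0L
  pooled <- vector("list", 4L)
  for (i in 1:4) {
    br <- stages[[i]]
    if (cfg$use_mdf) br <- forward(module$mods[[paste0("mdf", i)]], br)
    br <- forward(module$mods[[paste0("lateral", i)]], br)
    if (cfg$use_llm) br <- forward(module$mods[[paste0("llm", i)]], br)
    bd <- dim(tg_value(br))
    if (cfg$use_wssa && i <= 3L && bd[1] %% 2L == 0L && bd[2] %% 2L == 0L) {
      br <- forward(module$mods[[paste0("wssa", i)]], br)
      module$stats$wssa_calls <- module$stats$wssa_calls + 1L
    }
    pooled[[i]] <- op_gap(br)
  }
  feats <- op_concat_rows(pooled)
  forward(module$mods$classifier, feats)
}

#' Backbone stage outputs
#'
#' Runs only the backbone and returns the four stage feature maps (strides
#' 4/8/16/32).
#'
#' @param net an [msli_net()]
#' @param image array `(S, S, 3)` or `(S, S, 3, N)` with `S = input_size`;
#'   grayscale arrays `(S, S)` / `(S, S, 1)` are replicated to 3 channels
#' @return named list of arrays `c2`, `c3`, `c4`, `c5`
#' @export
backbone_stages <- function(net, image) {
  stopifnot(inherits(net, "msli_net"))
  x <- to_rgb_batch(image)
  d <- dim(x)
  if (d[1] != net$config$input_size || d[2] != net$config$input_size) {
    stop("expected input of spatial size ", net$config$input_size, "x",
         net$config$input_size, "; got ", d[1], "x", d[2])
  }
  set_training(net, FALSE)
  out <- with_no_grad(forward(net$mods$backbone, tg_const(x)))
  lapply(out, tg_value)
}

# Accept (H,W), (H,W,1), (H,W,3), (H,W,1,N), (H,W,3,N); return (H,W,3,N).
to_rgb_batch <- function(image) {
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  else if (length(d) == 3L) d <- c(d, 1L)
  x <- array(image, dim = d)
  if (d[3] == 1L) {
    # replicate the single grayscale channel three times
    x2 <- array(0, dim = c(d[1], d[2], 3L, d[4]))
    for (ch in 1:3) x2[, , ch, ] <- x[, , 1L, ]
    x <- x2
  } else if (d[3] != 3L) {
    stop("image must have 1 or 3 channels, got ", d[3])
  }
  x
}

#' Network forward pass on a plain image array
#'
#' @param net an [msli_net()]
#' @param image array `(S, S)` grayscale, `(S, S, 3)`, or batched versions
#' @param train logical; training mode (batch statistics, gradient tape)
#' @return numeric matrix of logits `(n_classes, N)`, or a length-`n_classes`
#'   vector for a single unbatched image
#' @export
msli_forward <- function(net, image, train = FALSE) {
  stopifnot(inherits(net, "msli_net"))
  d <- dim(image)
  single_image <- length(d) == 2L ||
    (length(d) == 3L && d[3] %in% c(1L, 3L))
  x <- to_rgb_batch(image)
  set_training(net, train)
  out <- if (train) forward(net, tg_const(x)) else
    with_no_grad(forward(net, tg_const(x)))
  v <- tg_value(out)
  if (single_image) as.vector(v) else v
}

#' Statistics recorded during the latest forward pass
#'
#' @param net an [msli_net()]
#' @return list with `wssa_calls`, the number of branches the wavelet
#'   attention block ran on
#' @export
last_forward_stats <- function(net) net$stats
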