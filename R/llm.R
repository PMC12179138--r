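# Multi-segmented lesion localization fusion (LLM).
#
# In retinal OCT the tissue band is horizontally elongated and typically
# spans about four of seven horizontal slabs of the image. The block splits
# the map into 7 row segments, takes the 4 sliding windows of 4 consecutive
# segments, refines each window with squeeze-and-excitation channel
# attention, re-stitches the refined rows into the untouched remainder of
# the map, projects with 1x1 conv + batch norm, and sums the four windowed
# branches with a fifth global branch (SE on the whole map).

#' Row windows of the 4-of-7 segment split
#'
#' Segment height is `floor(H / 7)`; remainder rows are appended to the last
#' segment, so the first six boundaries are deterministic. The four windows
#' cover segments 1-4, 2-5, 3-6 and 4-7.
#'
#' @param H feature-map height in rows; must be at least `n_segments`
#' @param n_segments number of horizontal segments (7)
#' @param window_segments segments per window (4)
#' @return data frame with `segment_index` and 0-based half-open row
#'   intervals `start_row`, `end_row`
#' @examples
#' segment_windows(56)  # (0,32) (8,40) (16,48) (24,56)
#' @export
segment_windows <- function(H, n_segments = 7L, window_segments = 4L) {
  H <- as.integer(H)
  if (window_segments >= n_segments) {
    stop("window_segments must be smaller than n_segments")
  }
  if (H < n_segments) {
    stop("height ", H, " is smaller than ", n_segments,
         " segments; upsample the feature map before the row split")
  }
  s <- H %/% n_segments
  bounds <- c((0:(n_segments - 1L)) * s, H)  # segment i spans [bounds[i], bounds[i+1])
  n_win <- n_segments - window_segments + 1L
  data.frame(
    segment_index = seq_len(n_win),
    start_row = bounds[seq_len(n_win)],
    end_row = bounds[seq_len(n_win) + window_segments]
  )
}

#' Multi-segmented lesion localization block
#'
#' @param channels channel count `C` (preserved)
#' @param se_reduction bottleneck ratio of the five SE attention blocks
#' @return an LLM module usable with [forward()] / [llm_forward()]
#' @export
llm_block <- function(channels, se_reduction = 16L) {
  m <- new_module("msli_llm")
  m$channels <- as.integer(channels)
  m$se_reduction <- as.integer(se_reduction)
  for (i in 1:5) {
    m$mods[[paste0("se", i)]] <- nn_se(channels, se_reduction)
    m$mods[[paste0("conv", i)]] <- nn_conv2d(channels, channels, 1L, bias = FALSE)
    m$mods[[paste0("bn", i)]] <- nn_batchnorm2d(channels)
  }
  m
}

#' @export
forward.msli_llm <- function(module, x, ...) {
  xv <- tg_value(x)
  d <- dim(xv)
  if (d[3] != module$channels) {
    stop("LLM configured for C = ", module$channels, ", input has ", d[3])
  }
  win <- segment_windows(d[1])
  acc <- NULL
  for (i in 1:4) {
    rows <- (win$start_row[i] + 1L):win$end_row[i]
    sub <- op_rows_crop(x, rows)
    ref <- forward(module$mods[[paste0("se", i)]], sub)
    full <- op_rows_stitch(x, ref, rows)
    out <- forward(module$mods[[paste0("bn", i)]],
                   forward(module$mods[[paste0("conv", i)]], full))
    acc <- if (is.null(acc)) out else op_add(acc, out)
  }
  g <- forward(module$mods$bn5,
               forward(module$mods$conv5,
                       forward(module$mods$se5, x)))
  op_add(acc, g)
}

#' Squeeze-and-excitation refinement on a plain array
#'
#' @param se an [nn_se()] block
#' @param x array `(H, W, C)` or `(H, W, C, N)`
#' @param train logical
#' @return array of the same shape, channelwise rescaled by gates in (0, 1)
#' @export
se_refine <- function(se, x, train = FALSE) {
  stopifnot(inherits(se, "nn_se"))
  run_module(se, x, train)
}

#' Full LLM forward pass on a plain array
#'
#' @param block an [llm_block()]
#' @param x array `(H, W, C)` or `(H, W, C, N)` with `H >= 7`
#' @param train logical
#' @return array of the same shape as `x`
#' @export
llm_forward <- function(block, x, train = FALSE) {
  stopifnot(inherits(block, "msli_llm"))
  run_module(block, x, train)
}
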