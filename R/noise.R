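# Multiplicative speckle model and PSNR.
#
# Coherent imaging carries multiplicative granular noise: F = g (1 + u) with
# u ~ Normal(0, sigma^2) i.i.d. per pixel, so the local noise variance grows
# with the local gray value. PSNR quantifies the resulting degradation.

#' Add multiplicative speckle noise to an image
#'
#' `F = g * (1 + u)` with `u ~ N(0, sigma^2)`; the result is clipped to
#' `[0, max_value]` unless `clip = FALSE` (the pre-clip field is what the
#' moment identity `E[(F - g)^2] = sigma^2 * mean(g^2)` refers to).
#'
#' @param g numeric image (any shape) with values in `[0, max_value]`
#' @param sigma noise standard deviation (> 0)
#' @param seed optional integer seed for reproducible noise
#' @param max_value dynamic ceiling of the image (default 1)
#' @param clip clip the noisy image back into `[0, max_value]`
#' @return noisy image of the same shape as `g`
#' @export
add_speckle <- function(g, sigma, seed = NULL, max_value = 1, clip = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  if (!all(is.finite(g))) stop("image contains non-finite values")
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::rnorm(length(g), mean = 0, sd = sigma)
  f <- g * (1 + u)
  if (clip) f <- pmin(pmax(f, 0), max_value)
  if (!is.null(dim(g))) dim(f) <- dim(g)
  f
}

#' Peak signal-to-noise ratio in decibels
#'
#' Standard definition `20 * log10(max_value / sqrt(MSE))`, equivalently
#' `10 * log10(max_value^2 / MSE)`. `strict = TRUE` instead evaluates
#' `20 * log10(max_value / MSE)` (MSE not root-MSE), an alternative reading
#' of the ratio sometimes seen in print. Identical images return `Inf`.
#'
#' @param g,f reference and degraded images of identical shape
#' @param max_value dynamic ceiling (default 1)
#' @param strict use the non-root variant
#' @return PSNR in dB
#' @export
psnr <- function(g, f, max_value = 1, strict = FALSE) {
  if (!identical(dim(g), dim(f)) || length(g) != length(f)) {
    stop("images differ in shape")
  }
  mse <- mean((as.numeric(g) - as.numeric(f))^2)
  if (mse == 0) return(Inf)
  if (strict) 20 * log10(max_value / mse) else 10 * log10(max_value^2 / mse)
}

#' Speckle-robustness sweep of a trained classifier
#'
#' The model is assumed clean-trained; noise is injected into the test
#' images only. For each sigma the test set is corrupted with a per-sigma
#' derived seed (`seed + round(100 * sigma)`), the dataset-mean PSNR against
#' the clean images and the classification accuracy are recorded.
#'
#' @param net a trained [msli_net()]
#' @param images list of grayscale test matrices in `[0, 1]`
#' @param labels integer labels in `[0, n_classes)`
#' @param sigmas noise levels; default the five-level sweep 0.1..0.5
#' @param seed base seed for the noise draws
#' @param norm list with `mean` and `sd` used to standardize model inputs
#' @param batch_size inference batch size
#' @param file optional path; the table is also written as CSV
#' @param pooled_psnr average PSNR per image (default) or over the pooled
#'   pixel population
#' @return data frame with columns `sigma`, `psnr_db`, `accuracy`
#' @export
robustness_protocol <- function(net, images, labels,
                                sigmas = seq(0.1, 0.5, by = 0.1), seed = 1L,
                                norm = NULL, batch_size = 8L, file = NULL,
                                pooled_psnr = FALSE) {
  if (length(sigmas) == 0L) stop("empty sigma list")
  if (any(sigmas <= 0)) stop("all sigma values must be positive")
  rows <- vector("list", length(sigmas))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    set.seed(as.integer(seed) + as.integer(round(100 * s)))
    noisy <- lapply(images, function(g) {
      f <- g * (1 + stats::rnorm(length(g), sd = s))
      f <- pmin(pmax(f, 0), 1)
      dim(f) <- dim(g)
      f
    })
    if (pooled_psnr) {
      mse <- mean(vapply(seq_along(images),
                         function(i) mean((images[[i]] - noisy[[i]])^2),
                         numeric(1)))
      p <- 10 * log10(1 / mse)
    } else {
      p <- mean(vapply(seq_along(images),
                       function(i) psnr(images[[i]], noisy[[i]]),
                       numeric(1)))
    }
    pred <- predict_labels(net, noisy, norm = norm, batch_size = batch_size)
    acc <- mean(pred == as.integer(labels))
    rows[[k]] <- data.frame(sigma = s, psnr_db = p, accuracy = acc)
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
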