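# Synthetic OCT-like image generator.
#
# Emulates the structural priors the architecture exploits: a horizontally
# elongated, layered tissue band whose vertical extent stays within 3/7 to
# 5/7 of the image (so the 4-of-7 row windows can cover it), one LOCAL
# class-specific lesion primitive per disease class (exercising the
# lesion-localization windows), and MULTIPLICATIVE speckle (exercising the
# wavelet attention and the noise protocol). Eight classes mirror the
# standard public eight-category OCT taxonomy; the default split fractions
# mirror its 2300/350/350 per-class convention.

OCT_CLASS_NAMES <- c("AMD", "CNV", "CSR", "DME", "DR", "DRUSEN", "MH", "NORMAL")

#' Synthetic dataset specification
#'
#' @param image_size square image extent in pixels
#' @param n_per_class images per class
#' @param n_classes fixed at 8
#' @param band_thickness_range per-column band thickness as a fraction of
#'   image height; together with the curvature amplitude the band's overall
#'   vertical footprint stays within `[3/7, 5/7]` of the height
#' @param band_center_jitter vertical jitter of the band center (fraction)
#' @param speckle_sigma standard deviation of the multiplicative speckle
#'   baked into every image
#' @param seed base seed; every image derives its own stream from it
#' @param split_fractions train/validation/test fractions (must sum to 1);
#'   default mirrors the 2300/350/350 convention
#' @return a spec list of class `msli_synth_spec`
#' @export
synthetic_spec <- function(image_size = 224L, n_per_class = 30L,
                           n_classes = 8L,
                           band_thickness_range = c(0.47, 0.58),
                           band_center_jitter = 0.05,
                           speckle_sigma = 0.08, seed = 1L,
                           split_fractions = c(2300, 350, 350) / 3000) {
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split_fractions must sum to 1")
  }
  if (n_classes != 8L) stop("the generator defines exactly 8 class archetypes")
  lo <- band_thickness_range[1]; hi <- band_thickness_range[2]
  if (lo < 3 / 7 || hi > 5 / 7 - 0.06) {
    stop("band_thickness_range must keep the band footprint (thickness plus ",
         "curvature, up to 0.06) within [3/7, 5/7] of the image height")
  }
  spec <- list(image_size = as.integer(image_size),
               n_per_class = as.integer(n_per_class), n_classes = 8L,
               band_thickness_range = band_thickness_range,
               band_center_jitter = band_center_jitter,
               speckle_sigma = speckle_sigma, seed = as.integer(seed),
               split_fractions = split_fractions)
  class(spec) <- "msli_synth_spec"
  spec
}

# Layered reflectivity profile of the tissue band as a function of relative
# depth r in [0, 1]: bright inner surface, darker plexiform body, a mid
# reflective stripe, and a bright outer (RPE-like) line.
band_profile <- function(r) {
  v <- rep(0.40, length(r))
  v[r < 0.95] <- 0.42
  v[r < 0.85] <- 0.40
  v[r < 0.55] <- 0.52
  v[r < 0.45] <- 0.36
  v[r < 0.08] <- 0.78
  v[r >= 0.88 & r < 0.97] <- 0.85
  v
}

#' Generate one synthetic OCT-like image
#'
#' Renders background, a smoothly curved layered band, the class-specific
#' lesion primitive, and multiplicative speckle. Deterministic given
#' `(class_id, seed)`.
#'
#' Archetypes: 0 dome elevation under the band (AMD), 1 bright irregular
#' intra-band blob (CNV), 2 dark intra-band fluid ellipse (CSR), 3 multiple
#' round cysts (DME), 4 band thinning (DR), 5 small bumps on the lower
#' boundary (DRUSEN), 6 full-thickness vertical notch (MH), 7 intact band
#' (NORMAL).
#'
#' @param class_id integer in `[0, 8)`
#' @param spec a [synthetic_spec()]
#' @param seed integer seed for this image's random stream
#' @return `image_size x image_size` matrix in `[0, 1]` with attributes
#'   `band_fraction` (vertical band footprint / height) and `class_id`
#' @export
generate_image <- function(class_id, spec = synthetic_spec(), seed = spec$seed) {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 0L || class_id > 7L) {
    stop("class_id must be an integer in [0, 8)")
  }
  set.seed(as.integer(seed))
  S <- spec$image_size
  xs <- seq_len(S)
  # background: dim, with a gentle vertical gradient
  img <- matrix(rep(0.04 + 0.04 * (xs - 1) / (S - 1), times = S), nrow = S)
  # band geometry
  thick <- stats::runif(1, spec$band_thickness_range[1],
                        spec$band_thickness_range[2]) * S
  center <- S * (0.5 + stats::runif(1, -1, 1) * spec$band_center_jitter)
  amp <- stats::runif(1, 0.01, 0.03) * S
  freq <- stats::runif(1, 0.6, 1.4)
  phase <- stats::runif(1, 0, 2 * pi)
  ctr <- center + amp * sin(2 * pi * freq * (xs - 1) / S + phase)
  top <- ctr - thick / 2
  bot <- ctr + thick / 2
  rowi <- matrix(xs, nrow = S, ncol = S)                 # row index per pixel
  topm <- matrix(top, nrow = S, ncol = S, byrow = TRUE)  # per-column band top
  botm <- matrix(bot, nrow = S, ncol = S, byrow = TRUE)
  inband <- rowi >= topm & rowi < botm
  rel <- (rowi - topm) / (botm - topm)                   # relative depth
  shade <- stats::runif(1, -0.03, 0.03)
  img[inband] <- band_profile(rel[inband]) + shade
  band_rows <- range(which(rowSums(inband) > 0))
  band_fraction <- (band_rows[2] - band_rows[1] + 1) / S

  # lesion primitive, placed around a random column in the central region
  cx <- stats::runif(1, 0.30, 0.70) * S
  cxi <- round(cx)
  colm <- matrix(xs, nrow = S, ncol = S, byrow = TRUE)
  ell <- function(cy0, cx0, ry, rx) {
    ((rowi - cy0) / ry)^2 + ((colm - cx0) / rx)^2 <= 1
  }
  bandc <- ctr[cxi]
  if (class_id == 0L) {          # AMD: dome elevation under the band
    base <- bot[cxi]
    dome <- ell(base, cx, 0.11 * S, 0.17 * S) & rowi >= botm
    img[dome] <- 0.70 + shade
  } else if (class_id == 1L) {   # CNV: bright irregular intra-band blob
    for (k in 1:3) {
      dy <- stats::runif(1, -0.08, 0.08) * S
      dx <- stats::runif(1, -0.08, 0.08) * S
      blob <- ell(bandc + dy, cx + dx, 0.07 * S, 0.09 * S) & inband
      img[blob] <- 0.92
    }
  } else if (class_id == 2L) {   # CSR: dark intra-band fluid pocket
    pocket <- ell(bandc + 0.08 * thick, cx, 0.30 * thick, 0.16 * S) & inband
    img[pocket] <- 0.06
  } else if (class_id == 3L) {   # DME: multiple round cysts
    ncyst <- sample(4:6, 1)
    for (k in seq_len(ncyst)) {
      dy <- stats::runif(1, -0.28, 0.28) * thick
      dx <- stats::runif(1, -0.22, 0.22) * S
      r <- stats::runif(1, 0.035, 0.055) * S
      cyst <- ell(bandc + dy, cx + dx, r, r) & inband
      img[cyst] <- 0.08
    }
  } else if (class_id == 4L) {   # DR: band thinning over a window
    w0 <- max(1L, round(cx - 0.16 * S)); w1 <- min(S, round(cx + 0.16 * S))
    thin <- colm >= w0 & colm <= w1 & rel > 0.45 & inband
    img[thin] <- 0.05 + 0.04 * (rowi[thin] - 1) / (S - 1)
  } else if (class_id == 5L) {   # DRUSEN: bumps on the lower boundary
    nb <- sample(3:5, 1)
    for (k in seq_len(nb)) {
      bx <- cx + stats::runif(1, -0.22, 0.22) * S
      bxi <- min(S, max(1L, round(bx)))
      bump <- ell(bot[bxi], bx, 0.045 * S, 0.035 * S) & rowi >= botm
      img[bump] <- 0.88
    }
  } else if (class_id == 6L) {   # MH: full-thickness vertical notch
    half <- 0.035 * S
    notch <- abs(colm - cx) <= half & rel < 0.62 & inband
    img[notch] <- 0.05
  }                              # class 7 NORMAL: intact band

  img <- pmin(pmax(img, 0), 1)
  img <- add_speckle(img, spec$speckle_sigma, max_value = 1)
  dim(img) <- c(S, S)
  attr(img, "band_fraction") <- band_fraction
  attr(img, "class_id") <- class_id
  img
}

# Largest-remainder apportionment of n items to fractions; ties favour
# later entries (so with the default fractions the test split absorbs the
# remainder seat).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, -seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a class-balanced labeled synthetic dataset
#'
#' @param spec a [synthetic_spec()]
#' @param merge_train_val fold the validation split into the training split
#'   (the merged-training convention)
#' @param dir optional directory: images are written as a class-per-directory
#'   PNG tree (`dir/<split>/<class>/img_<id>.png`) with a `manifest.csv`
#'   (`path,label,split`); requires the `png` package
#' @return object of class `msli_dataset`: list with `images` (list of
#'   matrices), `labels` (0-based integers), `split` (character), `manifest`
#'   (data frame), `class_names`, `spec`
#' @export
generate_dataset <- function(spec = synthetic_spec(), merge_train_val = FALSE,
                             dir = NULL) {
  if (spec$n_per_class < 8L) stop("n_per_class must be at least 8")
  counts <- largest_remainder(spec$n_per_class, spec$split_fractions)
  split_of <- rep(c("train", "val", "test"), counts)
  n_total <- spec$n_per_class * spec$n_classes
  images <- vector("list", n_total)
  labels <- integer(n_total)
  split <- character(n_total)
  seeds <- integer(n_total)
  k <- 0L
  for (cl in 0:(spec$n_classes - 1L)) {
    for (j in seq_len(spec$n_per_class)) {
      k <- k + 1L
      sd <- spec$seed + cl * 100003L + j * 131L
      images[[k]] <- generate_image(cl, spec, seed = sd)
      labels[k] <- cl
      split[k] <- split_of[j]
      seeds[k] <- sd
    }
  }
  if (merge_train_val) split[split == "val"] <- "train"
  manifest <- data.frame(
    id = seq_len(n_total),
    label = labels,
    class = OCT_CLASS_NAMES[labels + 1L],
    split = split,
    seed = seeds,
    band_fraction = vapply(images, function(im) attr(im, "band_fraction"),
                           numeric(1))
  )
  ds <- list(images = images, labels = labels, split = split,
             manifest = manifest, class_names = OCT_CLASS_NAMES, spec = spec)
  class(ds) <- "msli_dataset"
  if (!is.null(dir)) write_dataset_png(ds, dir)
  ds
}

write_dataset_png <- function(ds, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing a PNG tree requires the 'png' package")
  }
  paths <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    sub <- file.path(dir, ds$split[i], ds$class_names[ds$labels[i] + 1L])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, sprintf("img_%05d.png", i))
    png::writePNG(ds$images[[i]], paths[i])
  }
  man <- data.frame(path = paths, label = ds$labels, split = ds$split)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read a class-per-directory PNG tree back into a dataset
#'
#' Accepts the layout written by [generate_dataset()] (and any real dataset
#' arranged the same way): `dir/<split>/<class>/*.png` plus an optional
#' `manifest.csv`.
#'
#' @param dir dataset root
#' @return an `msli_dataset`
#' @export
read_image_dataset <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading a PNG tree requires the 'png' package")
  }
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no PNG files under ", dir)
  rel <- substring(files, nchar(dir) + 2L)
  parts <- strsplit(rel, "/", fixed = TRUE)
  split <- vapply(parts, `[`, "", 1L)
  cls <- vapply(parts, `[`, "", 2L)
  classes <- sort(unique(cls))
  labels <- match(cls, classes) - 1L
  images <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im
  })
  ds <- list(images = images, labels = labels, split = split,
             manifest = data.frame(path = files, label = labels, split = split),
             class_names = classes, spec = NULL)
  class(ds) <- "msli_dataset"
  ds
}

#' Extract one split of a dataset
#'
#' @param ds an `msli_dataset`
#' @param which `"train"`, `"val"` or `"test"`
#' @return list with `images` and `labels`
#' @export
dataset_split <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  sel <- ds$split == which
  list(images = ds$images[sel], labels = ds$labels[sel])
}
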