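# Training protocol: cross-entropy loss, Adam (beta1 0.9, beta2 0.999),
# fixed learning rate 0.001, batch size 64, 60 epochs, weight decay 1e-4,
# final-epoch weights used for testing, six independent repeats averaged.
# Inputs are standardized with mean/sd computed from the training split.

#' Training configuration
#'
#' Defaults follow the reference protocol exactly: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, fixed learning rate 0.001, batch size 64, 60 epochs,
#' weight decay 1e-4, cross-entropy loss, six repeats.
#'
#' @param lr learning rate
#' @param batch_size minibatch size
#' @param epochs training epochs; the final-epoch weights are the ones
#'   evaluated
#' @param beta1,beta2 Adam moment decays
#' @param weight_decay L2 coupling added to the gradient
#' @param loss only `"cross-entropy"` is defined
#' @param mixed_precision run convolutions in single precision (the
#'   reduced-precision training mode); off by default
#' @param n_repeats independent repeats; repeat `r` uses seed `seed + r - 1`
#' @param seed base seed
#' @param early_stop_train_acc optional running-training-accuracy level at
#'   which training halts early (NULL trains the full schedule)
#' @return a config list of class `msli_train_config`
#' @export
train_config <- function(lr = 0.001, batch_size = 64L, epochs = 60L,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-4,
                         loss = "cross-entropy", mixed_precision = FALSE,
                         n_repeats = 6L, seed = 1L,
                         early_stop_train_acc = NULL) {
  if (!identical(loss, "cross-entropy")) {
    stop("only cross-entropy loss is defined")
  }
  cfg <- list(lr = lr, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
              weight_decay = weight_decay, loss = loss,
              mixed_precision = isTRUE(mixed_precision),
              n_repeats = as.integer(n_repeats), seed = as.integer(seed),
              early_stop_train_acc = early_stop_train_acc)
  class(cfg) <- "msli_train_config"
  cfg
}

# Adam with additive (L2) weight decay.
adam_init <- function(params) {
  # p$v * 0 clones the exact shape (including a NULL dim for plain vectors)
  list(t = 0L,
       m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0))
}

adam_step <- function(params, st, lr, beta1, beta2, eps = 1e-8,
                      weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$v
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

# Mean/sd over the training pixels ("pre-calculated" normalization).
norm_stats <- function(images) {
  s <- 0; s2 <- 0; n <- 0
  for (im in images) {
    s <- s + sum(im); s2 <- s2 + sum(im^2); n <- n + length(im)
  }
  mu <- s / n
  sd <- sqrt(max(s2 / n - mu^2, 1e-12))
  list(mean = mu, sd = sd)
}

make_batch <- function(images, idx, norm) {
  S <- nrow(images[[idx[1]]])
  x <- array(0, dim = c(S, S, 3L, length(idx)))
  for (j in seq_along(idx)) {
    im <- (images[[idx[j]]] - norm$mean) / norm$sd
    for (ch in 1:3) x[, , ch, j] <- im
  }
  x
}

#' Train a network on labeled grayscale images
#'
#' @param net an [msli_net()]
#' @param images list of grayscale matrices in `[0, 1]`
#' @param labels integer labels in `[0, n_classes)`
#' @param config a [train_config()]
#' @param log_file optional path; one JSON line per epoch
#'   (`epoch`, `split`, `loss`, `accuracy`) is appended
#' @param verbose print one line per epoch
#' @return list with `history` (per-epoch data frame), `norm` (the input
#'   standardization statistics, needed at inference), `epochs_run`
#' @export
fit <- function(net, images, labels, config = train_config(),
                log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "msli_net"), inherits(config, "msli_train_config"))
  labels <- as.integer(labels)
  n <- length(images)
  norm <- norm_stats(images)
  params <- parameters(net)
  opt <- adam_init(params)
  set.seed(config$seed)
  hist <- vector("list", config$epochs)
  epochs_run <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      x <- make_batch(images, idx, norm)
      y <- labels[idx]
      set_training(net, TRUE)
      loss <- with_single_precision(single = config$mixed_precision, {
        out <- forward(net, tg_const(x))
        l <- op_softmax_ce(out, y)
        tg_backward(l)
        l
      })
      opt <- adam_step(params, opt, config$lr, config$beta1, config$beta2,
                       weight_decay = config$weight_decay)
      zero_grads(params)
      pred <- max.col(t(loss$probs)) - 1L
      tot_correct <- tot_correct + sum(pred == y)
      tot_loss <- tot_loss + as.numeric(loss$v) * length(idx)
    }
    acc <- tot_correct / n
    rec <- data.frame(epoch = epoch, split = "train",
                      loss = tot_loss / n, accuracy = acc)
    hist[[epoch]] <- rec
    epochs_run <- epoch
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE, sep = "")
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                      epoch, rec$loss, acc))
    }
    if (!is.null(config$early_stop_train_acc) &&
        acc >= config$early_stop_train_acc) break
  }
  set_training(net, FALSE)
  list(history = do.call(rbind, hist[seq_len(epochs_run)]), norm = norm,
       epochs_run = epochs_run)
}

#' Predict class labels for grayscale images
#'
#' @param net a trained [msli_net()]
#' @param images list of grayscale matrices
#' @param norm standardization statistics from [fit()] (NULL: compute from
#'   these images)
#' @param batch_size inference batch size
#' @return integer vector of 0-based predicted labels
#' @export
predict_labels <- function(net, images, norm = NULL, batch_size = 8L) {
  if (is.null(norm)) norm <- norm_stats(images)
  n <- length(images)
  preds <- integer(n)
  set_training(net, FALSE)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch_size - 1L, n)
    x <- make_batch(images, idx, norm)
    logits <- with_no_grad(forward(net, tg_const(x)))
    preds[idx] <- max.col(t(tg_value(logits))) - 1L
    i <- i + batch_size
  }
  preds
}

#' Evaluate a network on labeled images
#'
#' @inheritParams predict_labels
#' @param labels integer labels
#' @return an `msli_metrics` object (see [classification_metrics()])
#' @export
evaluate_model <- function(net, images, labels, norm = NULL, batch_size = 8L) {
  pred <- predict_labels(net, images, norm = norm, batch_size = batch_size)
  classification_metrics(as.integer(labels), pred, net$config$n_classes)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the model configuration, every parameter and
#' buffer, the input standardization statistics and the training seed, so
#' `load_checkpoint()` reconstructs a bitwise-identical model.
#'
#' @param net an [msli_net()]
#' @param path file path (RDS)
#' @param norm standardization statistics to embed
#' @param extra optional named list stored verbatim
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(net, path, norm = NULL, extra = list()) {
  obj <- list(config = net$config, state = module_state(net), norm = norm,
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: list with `net`, `norm`, `extra`
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- msli_net(obj$config)
  module_load_state(net, obj$state)
  list(net = net, norm = obj$norm, extra = obj$extra)
}
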