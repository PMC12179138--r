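# Classification metrics: accuracy plus macro-averaged precision,
# sensitivity (recall) and F1, derived from per-class confusion counts.
# Macro averaging is the natural contract for the balanced eight-class
# evaluation splits used throughout.

#' Confusion counts and macro-averaged classification metrics
#'
#' Accuracy is `n / N` (correct over total). Precision `TP / (TP + FP)`,
#' sensitivity `TP / (TP + FN)` and F1 (their harmonic mean) are computed
#' per class and macro-averaged. A class with zero support (or an undefined
#' ratio) contributes 0, with a warning.
#'
#' @param y_true,y_pred integer class labels in `[0, n_classes)`
#' @param n_classes number of classes
#' @return object of class `msli_metrics`: a list with `accuracy`,
#'   `precision`, `sensitivity`, `f1`, `averaging = "macro"`, the
#'   `confusion` matrix (rows = true, columns = predicted) and the
#'   `per_class` data frame of TP/FP/FN/TN counts
#' @export
classification_metrics <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes)) {
    stop("labels must lie in [0, ", n_classes, ")")
  }
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  cm <- matrix(as.numeric(cm), n_classes, n_classes,
               dimnames = list(true = lv, pred = lv))
  N <- length(y_true)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- N - tp - fp - fn
  support <- rowSums(cm)
  if (any(support == 0)) {
    warning("class(es) ", paste(lv[support == 0], collapse = ", "),
            " have zero support; they contribute 0 to the macro averages")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  f1 <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  out <- list(
    accuracy = sum(tp) / N,
    precision = mean(prec),
    sensitivity = mean(sens),
    f1 = mean(f1),
    averaging = "macro",
    confusion = cm,
    per_class = data.frame(class = lv, tp = tp, fp = fp, fn = fn, tn = tn,
                           support = support)
  )
  class(out) <- "msli_metrics"
  out
}

#' @export
print.msli_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f | macro sensitivity %.4f | macro F1 %.4f (N = %d)\n",
    x$accuracy, x$precision, x$sensitivity, x$f1, sum(x$per_class$support)))
  invisible(x)
}
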