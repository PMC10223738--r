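#' Confusion matrix and binary classification metrics
#'
#' Computes the confusion counts and the derived accuracy, recall
#' (sensitivity), precision, specificity, F1 and Matthews correlation
#' coefficient. Ratios with zero denominators are reported as `NaN` and
#' flagged in `undefined`, never silently zeroed.
#'
#' @param predicted,truth Equal-length binary (0/1) label vectors.
#' @param positive Value treated as the positive class (default 1:
#'   nodule / malignant).
#' @return An object of class `odnn_metrics`: a list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `recall`, `precision`, `specificity`, `f1`, `mcc`,
#'   and `undefined` (character vector naming any NaN metrics).
#' @export
confusion_and_metrics <- function(predicted, truth, positive = 1) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  p <- predicted == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  div <- function(a, b) if (b == 0) NaN else a / b
  accuracy <- div(tp + tn, tp + tn + fp + fn)
  recall <- div(tp, tp + fn)
  precision <- div(tp, tp + fp)
  specificity <- div(tn, tn + fp)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) NaN else (tp * tn - fp * fn) / denom
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, accuracy = accuracy,
              recall = recall, precision = precision,
              specificity = specificity, f1 = f1, mcc = mcc)
  out$undefined <- names(out)[vapply(out, function(x)
    is.numeric(x) && length(x) == 1 && is.nan(x), logical(1))]
  class(out) <- "odnn_metrics"
  out
}

#' @export
print.odnn_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.4f  recall %.4f  precision %.4f  specificity %.4f\n",
              x$accuracy, x$recall, x$precision, x$specificity))
  cat(sprintf("F1 %.4f  MCC %.4f\n", x$f1, x$mcc))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' F1 score from a (precision, recall) pair
#'
#' Harmonic mean `2*P*R/(P+R)`; accepts percentages or proportions (both
#' arguments on the same scale).
#'
#' @param precision,recall Scalars on a common scale.
#' @return F1 on the proportion scale (a percentage pair is rescaled).
#' @export
f1_from_pr <- function(precision, recall) {
  if (precision > 1 || recall > 1) {   # given as percentages
    precision <- precision / 100
    recall <- recall / 100
  }
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores, computing the true- and
#' false-positive rates; the AUC is the trapezoidal area, which gives tied
#' scores a half contribution (equivalently the rank-sum / Mann-Whitney
#' statistic).
#'
#' @param scores Finite numeric positive-class scores.
#' @param truth 0/1 labels of the same length.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == 1
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) stop("need both classes for a ROC curve")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & pos) / npos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !pos) / nneg, numeric(1))
  roc <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Write a metrics table as CSV
#'
#' One row per evaluated setting with the canonical column set:
#' accuracy, recall (sensitivity), precision, F1 score and MCC (accuracy,
#' recall and precision as percentages).
#'
#' @param rows Named list of `odnn_metrics` objects (names become the
#'   `work` column).
#' @param path CSV destination.
#' @return The data.frame written, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    m <- rows[[nm]]
    data.frame(work = nm,
               accuracy_pct = 100 * m$accuracy,
               recall_sensitivity_pct = 100 * m$recall,
               precision_pct = 100 * m$precision,
               f1_score = m$f1,
               mcc = m$mcc)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
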