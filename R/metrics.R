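# Confusion-matrix metrics and ROC/AUC.

#' Confusion matrix from counts or predictions
#'
#' Positive class is cancer (label 1) throughout.
#'
#' @param tp,tn,fp,fn Non-negative counts, or
#' @param pred,truth 0/1 vectors from which the counts are tallied.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                             pred = NULL, truth = NULL) {
  if (!is.null(pred)) {
    pred <- as.integer(pred); truth <- as.integer(truth)
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("confusion counts must be non-negative with a positive total", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity/recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, and
#' F-measure `2*precision*recall/(precision+recall)`.  A zero-denominator
#' ratio is reported as 0 and flagged in the `degenerate` attribute.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with one row per metric (`metric`, `value`), carrying a
#'   `degenerate` attribute naming any flagged metrics.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      return(0)
    }
    num / den
  }
  acc <- safe(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn, "accuracy")
  sens <- safe(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe(cm$tp, cm$tp + cm$fp, "precision")
  fmeas <- safe(2 * prec * sens, prec + sens, "f_measure")
  out <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "precision",
               "recall", "f_measure"),
    value = c(acc, sens, spec, prec, sens, fmeas)
  )
  attr(out, "degenerate") <- unique(flagged)
  out
}

#' ROC curve and AUC
#'
#' TPR/FPR computed at every distinct score threshold (ties included
#' simultaneously); AUC by the trapezoid rule.  The curve is a monotone
#' staircase from (0, 0) to (1, 1).
#'
#' @param scores Numeric classifier scores (higher = more cancer-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # aggregate ties: all samples at one score enter together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
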