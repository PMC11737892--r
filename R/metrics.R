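# Evaluation metrics implemented from first principles: accuracy, precision/
# recall/F1 (binary and macro), ROC/AUC by threshold sweep, PR curve, and the
# confusion matrix. Zero-denominator precision/recall/F1 follow the common
# score-0-with-warning convention.

#' Classification accuracy
#'
#' Fraction of exact label matches; in the binary case this equals
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean(as.character(y_true) == as.character(y_pred))
}

.binary_f1 <- function(y_true, y_pred, positive_label) {
  tp <- sum(y_true == positive_label & y_pred == positive_label)
  fp <- sum(y_true != positive_label & y_pred == positive_label)
  fn <- sum(y_true == positive_label & y_pred != positive_label)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warning("F1 undefined (zero denominator) for class '", positive_label,
            "'; scored as 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' Binary: `2 P R / (P + R)` with `P = TP/(TP+FP)`, `R = TP/(TP+FN)` for the
#' given positive class. Macro: the unweighted mean of one-vs-rest binary F1
#' over all classes observed in `y_true`, the usual choice under class
#' imbalance. Degenerate classes (no true and no predicted positives, or
#' P + R = 0) score 0 with a warning.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_label Positive class (required for `average = "binary"`).
#' @param average `"binary"` or `"macro"`.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(y_true, y_pred, positive_label = NULL,
                     average = c("binary", "macro")) {
  average <- match.arg(average)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (average == "binary") {
    if (is.null(positive_label)) stop("binary F1 requires positive_label")
    if (!positive_label %in% c(y_true, y_pred)) {
      stop("unknown positive_label: ", positive_label)
    }
    return(.binary_f1(y_true, y_pred, positive_label))
  }
  classes <- sort(unique(y_true))
  mean(vapply(classes, function(cl) .binary_f1(y_true, y_pred, cl), 0))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (descending),
#' records the true and false positive rates at each, and integrates the
#' trapezoidal area under the curve. Tied scores enter the sweep as one
#' block, so the AUC equals the tie-adjusted pairwise ranking probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param y_true Binary ground truth: logical, 0/1, or labels with
#'   `positive_label` naming the positive class.
#' @param scores Numeric scores, larger = more positive.
#' @param positive_label Positive class when `y_true` is not logical/0-1.
#' @return An object of class `roc_curve`: `thresholds` (descending, starting
#'   at `Inf`), `tpr`, `fpr`, and `auc`.
#' @export
roc_auc <- function(y_true, scores, positive_label = NULL) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  pos <- if (is.logical(y_true)) y_true
         else if (is.null(positive_label)) as.numeric(y_true) == 1
         else as.character(y_true) == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # one sweep point per distinct score (block ends)
  block_end <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(p)[block_end]
  fp <- cumsum(!p)[block_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[block_end]), tpr = tpr, fpr = fpr,
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", length(x$tpr), "points, AUC =", format(x$auc, digits = 6), "\n")
  invisible(x)
}

#' Precision-recall curve and average precision
#'
#' Threshold sweep companion to [roc_auc()]; average precision is the
#' step-wise integral sum((R_k - R_{k-1}) * P_k).
#'
#' @inheritParams roc_auc
#' @return List with `thresholds`, `precision`, `recall`,
#'   `average_precision`.
#' @export
pr_curve <- function(y_true, scores, positive_label = NULL) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  pos <- if (is.logical(y_true)) y_true
         else if (is.null(positive_label)) as.numeric(y_true) == 1
         else as.character(y_true) == positive_label
  n_pos <- sum(pos)
  if (n_pos == 0L || n_pos == length(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  block_end <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(p)[block_end]
  npred <- which(block_end)
  precision <- tp / npred
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(thresholds = s[block_end], precision = precision, recall = recall,
       average_precision = ap)
}

#' Confusion matrix
#'
#' Entry (i, j) counts cells with true label i predicted as label j; row sums
#' are the per-class supports. With `normalize = TRUE` rows are divided by
#' their support (empty rows stay 0), giving the per-class proportion view.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param labels Label universe ordering the rows/columns; defaults to the
#'   sorted union of observed values. A value outside `labels` is an error.
#' @param normalize Row-normalize to proportions.
#' @return Square matrix with `labels` dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL, normalize = FALSE) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  observed <- unique(c(y_true, y_pred))
  if (is.null(labels)) {
    labels <- sort(observed)
  } else if (!all(observed %in% labels)) {
    stop("label(s) outside the provided set: ",
         paste(setdiff(observed, labels), collapse = ", "))
  }
  cm <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(true = labels, predicted = labels))
  if (normalize) {
    rs <- rowSums(cm)
    cm <- cm / ifelse(rs == 0L, 1L, rs)
  }
  cm
}

#' Write an evaluation report (metrics JSON + confusion matrix TSV)
#'
#' @param y_true,y_pred Label vectors.
#' @param prefix Output path prefix.
#' @return Invisibly, the metric list.
#' @export
write_evaluation_report <- function(y_true, y_pred, prefix) {
  metrics <- list(n = length(y_true),
                  accuracy = accuracy(y_true, y_pred),
                  macro_f1 = suppressWarnings(
                    f1_score(y_true, y_pred, average = "macro")))
  jsonlite::write_json(metrics, paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  cm <- confusion_matrix(y_true, y_pred)
  utils::write.table(cm, paste0(prefix, "_confusion.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(metrics)
}
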