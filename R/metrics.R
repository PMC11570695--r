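# Confusion-matrix metrics: one-vs-rest TP/FP/FN/TN per class, precision,
# recall, F1 (harmonic mean), overall accuracy, and macro averages over
# the 16 classes.

#' Build a confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns).
#'
#' @param truth,estimate Equal-length label vectors (concentrations in
#'   mg/dL, or any common alphabet).
#' @param levels Class alphabet in display order; defaults to the sorted
#'   union of both vectors. Labels outside `levels` are an error.
#' @return An integer matrix of class `glu_confusion` with `counts[i, j]`
#'   = items of true class i predicted as j.
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  if (is.null(levels)) levels <- sort(unique(c(truth, estimate)))
  if (length(truth) > 0 && (!all(truth %in% levels) || !all(estimate %in% levels))) {
    abort("Labels found outside the class alphabet.")
  }
  cm <- table(
    factor(truth, levels = levels),
    factor(estimate, levels = levels)
  )
  cm <- matrix(as.integer(cm), nrow = length(levels),
    dimnames = list(truth = as.character(levels), estimate = as.character(levels))
  )
  structure(cm, class = c("glu_confusion", class(cm)))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0)) {
    abort("`cm` must be a square non-negative count matrix.")
  }
}

#' One-vs-rest counts for one class
#'
#' @param cm A confusion matrix (square count matrix).
#' @param class 1-based class position in the matrix.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
binary_counts <- function(cm, class) {
  check_cm(cm)
  if (!is_count(class) || class > nrow(cm)) {
    abort("`class` must index a row of the confusion matrix.")
  }
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  tibble(
    class = rownames(cm)[class] %||% as.character(class),
    tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), tn = as.numeric(tn)
  )
}

metric_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Precision, recall and F1 from one-vs-rest counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`. A zero denominator defines the metric as 0 (keeps
#' macro averages computable); this is reported with a message when it
#' triggers.
#'
#' @param counts A one-row tibble from [binary_counts()], or any list with
#'   elements `tp`, `fp`, `fn`.
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) abort("Counts must be non-negative.")
  if (tp + fp == 0 || tp + fn == 0) {
    inform("Zero-denominator metric defined as 0.")
  }
  p <- metric_ratio(tp, tp + fp)
  r <- metric_ratio(tp, tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble(precision = p, recall = r, f1 = f1)
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total: the fraction of items predicted into their true
#' class.
#'
#' @param cm A confusion matrix.
#' @export
overall_accuracy <- function(cm) {
  check_cm(cm)
  total <- sum(cm)
  if (total == 0) abort("Cannot compute accuracy of an empty confusion matrix.")
  sum(diag(cm)) / total
}

#' Full per-class metric report
#'
#' Per-class precision/recall/F1 plus overall accuracy and macro-averaged
#' (uniform over classes) summary metrics.
#'
#' @param cm A confusion matrix.
#' @return An object of class `glu_metrics`: list with `per_class`
#'   (tibble), `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
metrics_report <- function(cm) {
  check_cm(cm)
  per_class <- dplyr::bind_rows(lapply(seq_len(nrow(cm)), function(i) {
    counts <- binary_counts(cm, i)
    dplyr::bind_cols(counts, class_metrics(counts))
  }))
  structure(
    list(
      per_class = per_class,
      accuracy = overall_accuracy(cm),
      macro_precision = mean(per_class$precision),
      macro_recall = mean(per_class$recall),
      macro_f1 = mean(per_class$f1)
    ),
    class = "glu_metrics"
  )
}

#' @export
print.glu_metrics <- function(x, ...) {
  cat(sprintf(
    "<glu_metrics> accuracy %.3f | macro P %.3f R %.3f F1 %.3f (%d classes)\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
    nrow(x$per_class)
  ))
  invisible(x)
}
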