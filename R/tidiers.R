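# broom-style tidiers for the result objects.

#' @describeIn confusion_matrix Tidy a confusion matrix into long counts
#'   (`truth`, `estimate`, `n`).
#' @param x A `glu_confusion` object.
#' @param ... Unused.
#' @export
tidy.glu_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "estimate", "n")
  as_tibble(df)
}

#' @describeIn metrics_report Per-class metric rows.
#' @param x A `glu_metrics` object.
#' @param ... Unused.
#' @export
tidy.glu_metrics <- function(x, ...) x$per_class

#' @describeIn metrics_report One-row summary: accuracy and macro
#'   averages.
#' @export
glance.glu_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    n_classes = nrow(x$per_class),
    n = sum(x$per_class$tp[1], x$per_class$fp[1], x$per_class$fn[1], x$per_class$tn[1])
  )
}

#' @describeIn compliance_report Per-pair band verdicts.
#' @param x An `iso_report` object.
#' @param ... Unused.
#' @export
tidy.iso_report <- function(x, ...) x$pairs

#' @describeIn compliance_report One-row summary of the report.
#' @export
glance.iso_report <- function(x, ...) {
  tibble(
    n = nrow(x$pairs),
    compliance_fraction = x$compliance_fraction,
    pass = x$pass,
    r2_low = x$r2_low,
    r2_high = x$r2_high
  )
}

#' @describeIn train_model Long-format loss history (`epoch`, `curve`,
#'   `loss`).
#' @param x A `glucnn_history` tibble.
#' @param ... Unused.
#' @export
tidy.glucnn_history <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"epoch",
    names_to = "curve", values_to = "loss"
  )
}

#' @describeIn build_model One-row model summary.
#' @param x A `glucnn` model.
#' @param ... Unused.
#' @export
glance.glucnn <- function(x, ...) {
  tibble(
    parameters = x$param_count,
    classes = x$spec$classes,
    input_height = x$spec$input_size[1],
    input_width = x$spec$input_size[2],
    trained = x$trained
  )
}

#' @describeIn cross_validate Pooled per-item predictions.
#' @param x A `glucnn_cv` object.
#' @param ... Unused.
#' @export
tidy.glucnn_cv <- function(x, ...) x$predictions

#' @describeIn cross_validate One-row cross-validation summary.
#' @export
glance.glucnn_cv <- function(x, ...) {
  tibble(
    folds = nrow(x$fold_metrics),
    n = nrow(x$predictions),
    accuracy = overall_accuracy(x$confusion),
    fold_accuracy_sd = stats::sd(x$fold_metrics$accuracy)
  )
}
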