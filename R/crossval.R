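# Stratified k-fold cross-validation: each item is predicted exactly once
# by a model that never saw it, and the per-fold predictions are pooled
# into one confusion matrix.

#' Cross-validate the CNN
#'
#' Stratified k-fold cross-validation (default k = 10). Folds are assigned
#' class by class under the configuration seed; for each fold a fresh
#' model is initialised, trained on the remaining folds and evaluated on
#' the held-out fold. Predictions are pooled over folds.
#'
#' @param data Dataset tibble (`image` list-column + `concentration`).
#' @param spec A [cnn_spec()] describing the model to train per fold.
#' @param config A [training_config()]; `folds` and `seed` drive the
#'   partition.
#' @return An object of class `glucnn_cv`: list with `confusion` (pooled
#'   [confusion_matrix()]), `predictions` (tibble `row`, `fold`, `truth`,
#'   `estimate`), `fold_metrics` (tibble `fold`, `n`, `accuracy`) and the
#'   `config` used.
#' @export
cross_validate <- function(data, spec = cnn_spec_small(),
                           config = training_config()) {
  stopifnot(is.data.frame(data), "concentration" %in% names(data))
  k <- config$folds
  counts <- table(data$concentration)
  if (k > min(counts)) {
    abort(sprintf(
      "folds = %d exceeds the smallest class size (%d).", k, min(counts)
    ))
  }
  fold_of <- integer(nrow(data))
  withr::with_seed(derive_seed(config$seed, 43L), {
    for (ix in split(seq_len(nrow(data)), data$concentration)) {
      fold_of[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })

  levels <- sort(unique(data$concentration))
  preds <- vector("list", k)
  fold_metrics <- tibble(fold = seq_len(k), n = NA_integer_, accuracy = NA_real_)
  for (fold in seq_len(k)) {
    hold <- fold_of == fold
    model <- build_model(spec, seed = derive_seed(config$seed, 47L, fold))
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, 53L, fold)
    fit <- train_model(model, data[!hold, , drop = FALSE], config = fold_config)
    est <- predict(fit$model, data[hold, , drop = FALSE])$.pred_concentration
    preds[[fold]] <- tibble(
      row = which(hold), fold = fold,
      truth = data$concentration[hold], estimate = est
    )
    fold_metrics$n[fold] <- sum(hold)
    fold_metrics$accuracy[fold] <- mean(est == data$concentration[hold])
    inform(sprintf(
      "fold %d/%d: n = %d, accuracy = %.3f",
      fold, k, sum(hold), fold_metrics$accuracy[fold]
    ))
  }
  predictions <- dplyr::bind_rows(preds)
  structure(
    list(
      confusion = confusion_matrix(predictions$truth, predictions$estimate,
        levels = levels
      ),
      predictions = predictions,
      fold_metrics = fold_metrics,
      config = config
    ),
    class = "glucnn_cv"
  )
}

#' @export
print.glucnn_cv <- function(x, ...) {
  cat(sprintf(
    "<glucnn_cv> %d folds, %d items, pooled accuracy %.3f\n",
    nrow(x$fold_metrics), nrow(x$predictions), overall_accuracy(x$confusion)
  ))
  invisible(x)
}

#' Shuffle the labels of a dataset
#'
#' Breaks the image-label association by randomly permuting the
#' `concentration` column across rows (a negative control: a classifier
#' trained on shuffled labels should score at chance on held-out data).
#'
#' @param data Dataset tibble.
#' @param seed Integer seed.
#' @export
permute_labels <- function(data, seed = 1L) {
  perm <- withr::with_seed(derive_seed(seed, 59L), sample.int(nrow(data)))
  data$concentration <- data$concentration[perm]
  if ("class_index" %in% names(data)) {
    data$class_index <- data$class_index[perm]
  }
  data
}
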