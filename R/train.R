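# Training loop: stratified 80/20 split, mini-batch Adam on cross-entropy,
# per-epoch loss history on the training and validation sets.

#' Training configuration
#'
#' @param epochs Training epochs (default 35).
#' @param train_fraction Fraction of the data used for training (default
#'   0.8; the remaining 20% is the held-out test/validation set).
#' @param folds Folds for cross-validation (default 10).
#' @param seed Integer seed driving the split, weight initialisation,
#'   epoch shuffling and dropout.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size (the initial rate under a decaying
#'   schedule).
#' @param lr_schedule `"constant"`, or `"cosine"` for a smooth decay of
#'   the learning rate to zero over the configured epochs (helps short
#'   training budgets settle instead of oscillating between adjacent
#'   classes).
#' @param optimizer Optimiser name; only `"adam"` is implemented.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 35, train_fraction = 0.8, folds = 10,
                            seed = 1L, batch_size = 32,
                            learning_rate = 1e-3,
                            lr_schedule = c("constant", "cosine"),
                            optimizer = "adam") {
  lr_schedule <- match.arg(lr_schedule)
  if (!is_count(epochs)) abort("`epochs` must be a positive integer.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  if (!is_count(folds, min = 2)) abort("`folds` must be an integer >= 2.")
  if (!is_count(batch_size)) abort("`batch_size` must be a positive integer.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (!identical(optimizer, "adam")) abort("Only the \"adam\" optimizer is implemented.")
  structure(
    list(
      epochs = as.integer(epochs), train_fraction = train_fraction,
      folds = as.integer(folds), seed = as.integer(seed),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      lr_schedule = lr_schedule, optimizer = optimizer
    ),
    class = "training_config"
  )
}

#' Stratified train/test split
#'
#' Splits a labelled dataset class by class so that every class
#' contributes `train_fraction` of its items (to within one item) to the
#' training set; the two parts are disjoint and the split is seeded.
#'
#' @param data Dataset tibble with a `concentration` column.
#' @param train_fraction Training fraction per class.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(data), "concentration" %in% names(data))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  counts <- table(data$concentration)
  if (any(counts < 2)) {
    abort(sprintf(
      "Every class needs at least 2 items; class %s has %d.",
      names(counts)[which.min(counts)], min(counts)
    ))
  }
  idx_train <- withr::with_seed(derive_seed(seed, 11L), {
    unlist(lapply(split(seq_len(nrow(data)), data$concentration), function(ix) {
      n_tr <- round_half_up(train_fraction * length(ix))
      n_tr <- min(max(n_tr, 1), length(ix) - 1) # both parts non-empty
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(
    train = data[sort(idx_train), , drop = FALSE],
    test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE]
  )
}

dataset_xy <- function(data, model) {
  pos <- match(data$concentration, model$class_mapping$concentration)
  if (anyNA(pos)) {
    abort("Dataset contains concentrations outside the model's class mapping.")
  }
  list(
    x = stack_images(data$image, model$spec$input_size, model$input_stats),
    y = pos
  )
}

eval_loss <- function(model, x, y, batch_size = 64) {
  n <- dim(x)[4]
  total <- 0
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    logits <- glucnn_forward(model, x[, , , ix, drop = FALSE], training = FALSE)$logits
    total <- total + cross_entropy(logits, y[ix])$loss * length(ix)
  }
  total / n
}

#' Train the CNN
#'
#' Mini-batch Adam on the softmax cross-entropy, recording one training
#' loss (mean over that epoch's mini-batches) and one validation loss
#' (full inference-mode pass) per epoch. Fully seeded: identical data,
#' configuration and seed reproduce the history and the trained weights.
#'
#' @param model A `glucnn` from [build_model()].
#' @param train_data Dataset tibble (`image` list-column + `concentration`).
#' @param valid_data Optional validation tibble; the held-out 20% split in
#'   the standard workflow. `NULL` records `NA` validation losses.
#' @param config A [training_config()].
#' @return A list with the trained `model` and `history`, a tibble of
#'   class `glucnn_history` with columns `epoch`, `train_loss`,
#'   `valid_loss`.
#' @export
train_model <- function(model, train_data, valid_data = NULL,
                        config = training_config()) {
  stopifnot(inherits(model, "glucnn"), inherits(config, "training_config"))
  if (nrow(train_data) == 0) abort("`train_data` is empty.")
  if (is.null(model$input_stats)) {
    # feature-wise standardisation fitted on the training set only; stored
    # with the model so inference applies the identical transform
    model$input_stats <- input_statistics(train_data$image, model$spec$input_size)
  }
  tr <- dataset_xy(train_data, model)
  va <- if (!is.null(valid_data) && nrow(valid_data) > 0) {
    dataset_xy(valid_data, model)
  }
  n <- dim(tr$x)[4]
  params <- lapply(model$layers, function(l) l[intersect(names(l), c("W", "b", "gamma", "beta"))])
  opt <- lapply(params, adam_init)
  step <- 0L
  history <- tibble(
    epoch = seq_len(config$epochs),
    train_loss = NA_real_, valid_loss = NA_real_
  )

  withr::with_seed(derive_seed(config$seed, 29L), {
    for (epoch in seq_len(config$epochs)) {
      lr <- if (identical(config$lr_schedule, "cosine")) {
        config$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      } else {
        config$learning_rate
      }
      order <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- order[start:min(start + config$batch_size - 1, n)]
        fw <- glucnn_forward(model, tr$x[, , , ix, drop = FALSE], training = TRUE)
        model <- fw$model
        ce <- cross_entropy(fw$logits, tr$y[ix])
        if (!is.finite(ce$loss)) {
          abort(sprintf(
            "Training diverged (non-finite loss at epoch %d); lower the learning rate.",
            epoch
          ))
        }
        grads <- glucnn_backward(model, fw$caches, ce$grad)
        step <- step + 1L
        for (i in seq_along(grads)) {
          if (is.null(grads[[i]])) next
          for (nm in names(grads[[i]])) {
            upd <- adam_step(
              model$layers[[i]][[nm]], grads[[i]][[nm]], opt[[i]][[nm]],
              lr, step
            )
            model$layers[[i]][[nm]] <- upd$param
            opt[[i]][[nm]] <- upd$state
          }
        }
        epoch_loss <- epoch_loss + ce$loss
        n_batches <- n_batches + 1L
      }
      history$train_loss[epoch] <- epoch_loss / n_batches
      if (!is.null(va)) {
        history$valid_loss[epoch] <- eval_loss(model, va$x, va$y)
      }
    }
  })
  model$trained <- TRUE
  class(history) <- c("glucnn_history", class(history))
  list(model = model, history = history)
}
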