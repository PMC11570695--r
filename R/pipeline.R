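# End-to-end runner: generate (optional) -> load -> preprocess ->
# split/train or cross-validate -> evaluate, with every artifact written
# into a self-describing run directory.

#' Assemble a run configuration
#'
#' Single configuration object covering every stage, optionally seeded
#' from a YAML file (`yaml` sections: `generator`, `preprocessing`, `cnn`,
#' `training`, `evaluation`, `master_seed`); `...` overrides win over file
#' values which win over defaults. All per-stage seeds are derived from
#' `master_seed`.
#'
#' @param file Optional YAML configuration path.
#' @param small Use the desk-scale profile (small generator + small CNN,
#'   15 epochs) as the baseline before overrides?
#' @param ... Named overrides of top-level sections or `master_seed`,
#'   e.g. `training = list(epochs = 5)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(file = NULL, small = FALSE, ...) {
  base <- list(
    generator = list(enabled = TRUE),
    preprocessing = list(low_tail = 0.01, high_tail = 0.01, method = "bilinear"),
    cnn = list(),
    training = list(),
    evaluation = list(mode = "holdout", r2_method = "identity"),
    data_dir = NULL,
    master_seed = 1L
  )
  if (small) {
    base$generator <- c(base$generator, list(small = TRUE))
    base$cnn <- list(small = TRUE)
    base$training <- list(
      epochs = 15, learning_rate = 8e-3, lr_schedule = "cosine"
    )
  }
  if (!is.null(file)) {
    base <- modifyList(base, yaml::read_yaml(file))
  }
  overrides <- list(...)
  if (length(overrides)) base <- modifyList(base, overrides)
  structure(base, class = "run_config")
}

config_objects <- function(config) {
  seed <- as.integer(config$master_seed)
  gen_args <- config$generator
  gen_small <- isTRUE(gen_args$small)
  gen_args$enabled <- NULL
  gen_args$small <- NULL
  gen_args$master_seed <- gen_args$master_seed %||% derive_seed(seed, 101L)
  if (is.character(gen_args$cameras)) {
    # YAML configs name cameras; resolve against the built-in profiles
    profiles <- camera_profiles()
    gen_args$cameras <- profiles[match(gen_args$cameras, profiles$camera), ]
  }
  gen <- do.call(if (gen_small) generator_config_small else generator_config, gen_args)

  cnn_args <- config$cnn
  cnn_small <- isTRUE(cnn_args$small)
  cnn_args$small <- NULL
  if (is.null(cnn_args$concentrations)) {
    cnn_args$classes <- length(gen$concentrations)
    cnn_args$concentrations <- gen$concentrations
  }
  if (cnn_small && is.null(cnn_args$input_size)) {
    cnn_args$input_size <- c(32, 32)
  }
  spec <- do.call(if (cnn_small) cnn_spec_small else cnn_spec, cnn_args)

  train_args <- config$training
  train_args$seed <- train_args$seed %||% derive_seed(seed, 103L)
  train <- do.call(training_config, train_args)

  list(generator = gen, spec = spec, training = train)
}

write_confusion_csv <- function(cm, path) {
  df <- as.data.frame.matrix(cm)
  df <- cbind(truth = rownames(cm), df)
  readr::write_csv(as_tibble(df), path)
}

#' Run the full pipeline
#'
#' Executes the configured stages and writes a self-describing run
#' directory: `manifest.csv`, `history.csv`, `confusion_matrix.csv`,
#' `metrics.csv`, `iso_report.json`, `provenance.yaml`, plus the trained
#' model (`model.rds`). Rerunning with an identical configuration and
#' master seed reproduces the confusion matrix and reports.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @return An object of class `glucopipe_run`: list with `confusion`
#'   (pooled or held-out [confusion_matrix()]), `metrics`
#'   ([metrics_report()]), `iso` ([compliance_report()]), `history`,
#'   `model`, `paths`.
#' @export
run_pipeline <- function(config = run_config(small = TRUE), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  objs <- config_objects(config)

  stage <- function(name, expr) {
    inform(sprintf("[%s] starting", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  data_dir <- config$data_dir %||% file.path(out_dir, "dataset")
  manifest <- NULL
  if (isTRUE(config$generator$enabled)) {
    manifest <- stage("generate", generate_dataset(objs$generator, data_dir))
  }
  data <- stage("load", load_dataset(data_dir,
    concentrations = objs$generator$concentrations
  ))
  if (is.null(manifest)) {
    manifest <- dplyr::select(data, "path", "concentration", "class_index")
  }

  data <- stage("preprocess", preprocess_dataset(
    data,
    low_tail = config$preprocessing$low_tail,
    high_tail = config$preprocessing$high_tail,
    size = objs$spec$input_size,
    method = config$preprocessing$method
  ))

  mode <- config$evaluation$mode %||% "holdout"
  if (mode == "holdout") {
    parts <- stage("split", split_dataset(
      data,
      train_fraction = objs$training$train_fraction,
      seed = objs$training$seed
    ))
    model <- build_model(objs$spec, seed = derive_seed(objs$training$seed, 7L))
    fit <- stage("train", train_model(model, parts$train,
      valid_data = parts$test, config = objs$training
    ))
    est <- stage("predict", predict(fit$model, parts$test)$.pred_concentration)
    confusion <- confusion_matrix(parts$test$concentration, est,
      levels = objs$spec$concentrations
    )
    history <- fit$history
    truth <- parts$test$concentration
    model_out <- fit$model
  } else if (mode == "crossval") {
    cv <- stage("crossval", cross_validate(data,
      spec = objs$spec,
      config = objs$training
    ))
    confusion <- cv$confusion
    history <- cv$fold_metrics
    est <- cv$predictions$estimate
    truth <- cv$predictions$truth
    model_out <- cv
  } else {
    abort(sprintf("Unknown evaluation mode '%s'.", mode))
  }

  metrics <- stage("evaluate", metrics_report(confusion))
  iso <- stage("iso", compliance_report(
    tibble(truth = truth, estimate = est),
    r2_method = config$evaluation$r2_method %||% "identity"
  ))

  paths <- list(
    manifest = file.path(out_dir, "manifest.csv"),
    history = file.path(out_dir, "history.csv"),
    confusion = file.path(out_dir, "confusion_matrix.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    iso = file.path(out_dir, "iso_report.json"),
    provenance = file.path(out_dir, "provenance.yaml"),
    model = file.path(out_dir, "model.rds")
  )
  readr::write_csv(manifest, paths$manifest)
  readr::write_csv(history, paths$history)
  write_confusion_csv(confusion, paths$confusion)
  readr::write_csv(
    dplyr::bind_cols(
      metrics$per_class,
      tibble(
        accuracy = metrics$accuracy,
        macro_precision = metrics$macro_precision,
        macro_recall = metrics$macro_recall,
        macro_f1 = metrics$macro_f1
      )[rep(1, nrow(metrics$per_class)), ]
    ),
    paths$metrics
  )
  jsonlite::write_json(
    list(
      compliance_fraction = iso$compliance_fraction,
      pass = iso$pass,
      r2_low = iso$r2_low,
      r2_high = iso$r2_high,
      absolute_band = iso$absolute_band,
      relative_band = iso$relative_band,
      threshold = iso$threshold,
      pairs = iso$pairs
    ),
    paths$iso,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  yaml::write_yaml(
    list(
      config = unclass(config),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("glucopipe"))
    ),
    paths$provenance
  )
  saveRDS(model_out, paths$model)

  structure(
    list(
      confusion = confusion, metrics = metrics, iso = iso,
      history = history, model = model_out, paths = paths
    ),
    class = "glucopipe_run"
  )
}

#' @export
print.glucopipe_run <- function(x, ...) {
  cat("<glucopipe_run>\n")
  print(x$metrics)
  print(x$iso)
  invisible(x)
}
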