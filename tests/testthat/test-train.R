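# Training behaviour on memorisable low-noise synthetic data. Kept small:
# 4 classes, a handful of images, a tiny spec.

tiny_spec <- function(classes = 4) {
  cnn_spec(
    input_size = c(16, 16), conv_filters = c(4, 8), stride = 2,
    inter_block_softmax = FALSE, dense_units = 16, dropout_rate = 0,
    classes = classes, concentrations = seq(50, by = 50, length.out = classes)
  )
}

tiny_dataset <- function(n_per_class = 6, classes = 4, seed = 1) {
  conc <- seq(50, by = 50, length.out = classes)
  level <- seq(40, 220, length.out = classes)
  rows <- list()
  for (i in seq_along(conc)) {
    for (r in seq_len(n_per_class)) {
      img <- withr::with_seed(derive_seed(seed, i, r), {
        round_half_up(pmin(pmax(
          matrix(level[i] + rnorm(256, sd = 4), 16, 16), 0
        ), 255))
      })
      storage.mode(img) <- "integer"
      rows[[length(rows) + 1]] <- tibble::tibble(
        concentration = conc[i], image = list(img)
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the loss history has exactly one entry per epoch", {
  data <- tiny_dataset()
  cfg1 <- training_config(epochs = 1, seed = 2, batch_size = 8)
  fit1 <- train_model(build_model(tiny_spec(), seed = 2), data, config = cfg1)
  expect_equal(nrow(fit1$history), 1)

  cfg5 <- training_config(epochs = 5, seed = 2, batch_size = 8)
  fit5 <- train_model(build_model(tiny_spec(), seed = 2), data,
    valid_data = data, config = cfg5
  )
  expect_equal(fit5$history$epoch, 1:5)
  expect_equal(sum(!is.na(fit5$history$train_loss)), 5)
  expect_equal(sum(!is.na(fit5$history$valid_loss)), 5)
  expect_true(all(fit5$history$train_loss >= 0))
})

test_that("training memorises low-noise synthetic data", {
  data <- tiny_dataset(n_per_class = 8)
  cfg <- training_config(
    epochs = 30, seed = 3, batch_size = 8, learning_rate = 5e-3
  )
  fit <- train_model(build_model(tiny_spec(), seed = 3), data,
    valid_data = data, config = cfg
  )
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.1 * h$train_loss[1])
  expect_lt(h$train_loss[nrow(h)], 0.1)
  # a well-trained model reproduces the training labels
  pred <- predict(fit$model, data)
  expect_equal(pred$.pred_concentration, data$concentration)
})

test_that("training is reproducible under a fixed seed", {
  data <- tiny_dataset()
  cfg <- training_config(epochs = 3, seed = 11, batch_size = 8)
  f1 <- train_model(build_model(tiny_spec(), seed = 7), data,
    valid_data = data, config = cfg
  )
  f2 <- train_model(build_model(tiny_spec(), seed = 7), data,
    valid_data = data, config = cfg
  )
  expect_identical(f1$history, f2$history)
  expect_identical(
    predict(f1$model, data)$.pred_concentration,
    predict(f2$model, data)$.pred_concentration
  )
})

test_that("divergent training aborts with a diagnostic", {
  data <- tiny_dataset(n_per_class = 2)
  # a step size this large overflows the dense stack to non-finite logits
  cfg <- training_config(epochs = 3, seed = 1, batch_size = 4, learning_rate = 1e155)
  expect_error(
    train_model(build_model(tiny_spec(), seed = 1), data, config = cfg),
    "diverged"
  )
})

test_that("training configuration is validated", {
  expect_error(training_config(epochs = 0))
  expect_error(training_config(train_fraction = 1))
  expect_error(training_config(folds = 1))
  expect_error(training_config(optimizer = "sgd"), "adam")
})
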