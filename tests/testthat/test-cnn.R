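test_that("the rectifier clips negatives and passes positives", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(5), 5)
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
})

test_that("the closed-form layer count matches hand arithmetic", {
  # one 3x3 conv block, 1 input channel, 16 filters: (3*3*1 + 1) * 16 = 160
  spec <- cnn_spec(
    input_size = c(16, 16), conv_filters = 16, dense_units = integer(0),
    classes = 2, concentrations = c(50, 60), dropout_rate = 0
  )
  # conv 160 + batchnorm 32 + final dense (16*16*16 + 1) * 2
  expect_equal(cnn_parameter_count(spec), 160 + 32 + (16 * 16 * 16 + 1) * 2)
})

test_that("analytic parameter count matches the allocated weight store", {
  set.seed(42)
  for (i in 1:5) {
    spec <- cnn_spec(
      input_size = c(sample(12:24, 1), sample(12:24, 1)),
      conv_filters = sample(2:8, 2),
      kernel_size = sample(c(3, 5), 1),
      stride = sample(1:2, 1),
      inter_block_softmax = sample(c(TRUE, FALSE), 1),
      dense_units = sample(4:32, 1),
      classes = 4,
      concentrations = c(50, 100, 150, 200)
    )
    model <- build_model(spec, seed = i)
    expect_equal(model_parameter_total(model), cnn_parameter_count(spec))
  }
})

test_that("the default full-size architecture exceeds 75 million parameters", {
  expect_gt(cnn_parameter_count(cnn_spec()), 75e6)
})

test_that("softmax outputs are a probability simplex for random inputs", {
  spec <- cnn_spec_small(classes = 16)
  model <- build_model(spec, seed = 3)
  set.seed(9)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    probs <- as.numeric(predict(model, img)[, -(1:2)])
    expect_true(all(probs >= 0))
    expect_lt(abs(sum(probs) - 1), 1e-6)
  }
})

test_that("inference is deterministic and ties break to the lowest class index", {
  model <- build_model(cnn_spec_small(), seed = 5)
  img <- matrix(128L, 32, 32)
  expect_identical(predict(model, img), predict(model, img))
  # a literal tie: which.max picks the first (lowest) index
  expect_equal(which.max(c(0.3, 0.3, 0.2)), 1)
})

test_that("invalid specifications are rejected", {
  expect_error(cnn_spec(classes = 0))
  expect_error(cnn_spec(kernel_size = 0), "Kernel")
  expect_error(cnn_spec(dropout_rate = 1), "dropout")
  expect_error(cnn_spec(conv_filters = integer(0)))
})

test_that("prediction rejects inputs of the wrong size", {
  model <- build_model(cnn_spec_small(), seed = 1)
  expect_error(predict(model, matrix(0L, 10, 10)), "expects")
})

test_that("stratified splitting hits the configured proportions per class", {
  data <- tibble::tibble(
    id = 1:1440,
    concentration = rep(seq(50, 200, 10), each = 90),
    image = replicate(1440, matrix(0L, 2, 2), simplify = FALSE)
  )
  parts <- split_dataset(data, train_fraction = 0.8, seed = 4)
  expect_equal(nrow(parts$train), 1152)
  expect_equal(nrow(parts$test), 288)
  expect_true(all(table(parts$train$concentration) == 72))
  expect_true(all(table(parts$test$concentration) == 18))
  expect_length(intersect(parts$train$id, parts$test$id), 0)
  expect_setequal(c(parts$train$id, parts$test$id), data$id)

  again <- split_dataset(data, train_fraction = 0.8, seed = 4)
  expect_identical(parts$train$id, again$train$id)
  expect_identical(parts$test$id, again$test$id)
})

test_that("minimal stratification gives one item per side", {
  data <- tibble::tibble(
    concentration = rep(c(50, 60), each = 2),
    image = replicate(4, matrix(0L, 2, 2), simplify = FALSE)
  )
  parts <- split_dataset(data, train_fraction = 0.5, seed = 1)
  expect_true(all(table(parts$train$concentration) == 1))
  expect_true(all(table(parts$test$concentration) == 1))
  solo <- tibble::tibble(concentration = c(50, 50, 60), image = data$image[1:3])
  expect_error(split_dataset(solo), "at least 2")
})
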