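test_that("confusion matrix counts true-vs-predicted pairs", {
  levels <- seq(50, 200, 10)
  truth <- rep(levels, each = 10)
  cm <- confusion_matrix(truth, truth, levels = levels)
  expect_true(all(diag(cm) == 10))
  expect_equal(sum(cm), 160)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  empty <- confusion_matrix(numeric(0), numeric(0), levels = levels)
  expect_true(all(empty == 0))

  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(50, 75), c(50, 50), levels = levels), "alphabet")
})

test_that("confusion matrix agrees with exhaustive pair counting", {
  set.seed(21)
  labels <- seq(50, 120, 10)
  truth <- sample(labels, 50, replace = TRUE)
  est <- sample(labels, 50, replace = TRUE)
  cm <- confusion_matrix(truth, est, levels = labels)
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      expect_equal(
        cm[i, j],
        sum(truth == labels[i] & est == labels[j])
      )
    }
  }
})

test_that("one-vs-rest counts follow the 2x2 hand tally", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2) # rows truth: [[8,2],[1,9]]
  bc <- binary_counts(cm, 1)
  expect_equal(bc$tp, 8)
  expect_equal(bc$fn, 2)
  expect_equal(bc$fp, 1)
  expect_equal(bc$tn, 9)
  # partition identity for every class of a random matrix
  set.seed(3)
  rcm <- random_confusion(6)
  for (i in 1:6) {
    b <- binary_counts(rcm, i)
    expect_equal(b$tp + b$fp + b$fn + b$tn, sum(rcm))
  }
  expect_error(binary_counts(rcm, 7), "index")
})

test_that("precision/recall/F1 reproduce hand-evaluated cases", {
  # harmonic mean: P = 8/9, R = 0.8 -> F1 = 0.84210...
  m <- class_metrics(list(tp = 8, fp = 1, fn = 2))
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  # published worked example: P = 1, R = 0.92 -> F1 = 0.96 at two decimals
  f1 <- class_metrics(list(tp = 92, fp = 0, fn = 8))$f1
  expect_equal(round(f1, 2), 0.96)
  # zero-denominator counts define metrics as 0
  z <- suppressMessages(class_metrics(list(tp = 0, fp = 0, fn = 0)))
  expect_equal(unlist(z), c(precision = 0, recall = 0, f1 = 0))
})

test_that("overall accuracy is the trace over the total", {
  expect_equal(overall_accuracy(diag(5) * 7), 1)
  cm <- matrix(c(8, 1, 2, 9), 2, 2, byrow = TRUE)
  expect_equal(overall_accuracy(cm), 17 / 20)
  # invariant under simultaneous row/column permutation
  p <- c(2, 1)
  expect_equal(overall_accuracy(cm[p, p]), 17 / 20)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("metrics agree with the pair-enumeration oracle on random matrices", {
  set.seed(77)
  for (case in 1:100) {
    k <- sample(2:8, 1)
    cm <- random_confusion(k)
    if (sum(cm) == 0) next
    oracle <- oracle_metrics(cm)
    expect_equal(overall_accuracy(cm), oracle$accuracy, tolerance = 1e-12)
    report <- suppressMessages(metrics_report(cm))
    for (i in seq_len(k)) {
      m <- suppressMessages(class_metrics(binary_counts(cm, i)))
      expect_equal(m$precision, oracle$per_class[i, "precision"],
        tolerance = 1e-12, ignore_attr = TRUE
      )
      expect_equal(m$recall, oracle$per_class[i, "recall"],
        tolerance = 1e-12, ignore_attr = TRUE
      )
      expect_equal(m$f1, oracle$per_class[i, "f1"],
        tolerance = 1e-12, ignore_attr = TRUE
      )
    }
    expect_equal(report$macro_f1, mean(oracle$per_class[, "f1"]), tolerance = 1e-12)
  }
})

test_that("F1 lies between precision and recall", {
  set.seed(13)
  for (case in 1:50) {
    counts <- list(
      tp = sample(1:50, 1), fp = sample(0:50, 1), fn = sample(0:50, 1)
    )
    m <- class_metrics(counts)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("tidiers expose the report as tibbles", {
  cm <- confusion_matrix(c(50, 50, 60), c(50, 60, 60), levels = c(50, 60))
  td <- tidy(cm)
  expect_equal(sum(td$n), 3)
  rep <- metrics_report(cm)
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_equal(g$accuracy, 2 / 3)
  expect_equal(g$n_classes, 2)
})
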