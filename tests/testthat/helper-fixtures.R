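# Shared fixtures: all synthetic, built in code at test time.

# Desk-scale dataset already preprocessed to the small classifier input.
# Cached per session so the training-heavy tests share one generation.
small_processed_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(master_seed = 7) {
    key <- as.character(master_seed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("glucopipe-small-", master_seed))
      if (!dir.exists(dir)) {
        suppressMessages(generate_dataset(
          generator_config_small(master_seed = master_seed), dir
        ))
      }
      data <- suppressMessages(load_dataset(dir))
      cache[[key]] <- preprocess_dataset(data, size = c(32, 32))
    }
    cache[[key]]
  }
})

# Tiny deterministic RGB array fixture
tiny_rgb <- function(h = 4, w = 4, r = 10, g = 20, b = 30) {
  array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3))
}

# independent sorted-multiset quantile (linear interpolation), used as the
# oracle for stretch_contrast
oracle_quantile <- function(x, p) {
  s <- sort(as.vector(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_stretch <- function(img, low = 0.01, high = 0.01) {
  q1 <- oracle_quantile(img, low)
  q2 <- oracle_quantile(img, 1 - high)
  if (q1 >= q2) return(img)
  out <- img
  for (i in seq_along(img)) {
    v <- min(max(img[i], q1), q2)
    v <- (v - q1) / (q2 - q1) * 255
    out[i] <- sign(v) * floor(abs(v) + 0.5)
  }
  storage.mode(out) <- "integer"
  out
}

# independent scalar bilinear interpolation with half-pixel centres
oracle_bilinear <- function(img, oh, ow) {
  out <- matrix(0, oh, ow)
  h <- nrow(img)
  w <- ncol(img)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      sy <- min(max((i - 0.5) * h / oh - 0.5, 0), h - 1)
      sx <- min(max((j - 0.5) * w / ow - 0.5, 0), w - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      fy <- sy - y0; fx <- sx - x0
      v <- (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
      out[i, j] <- min(max(floor(v + 0.5), 0), 255)
    }
  }
  out
}

# exhaustive pair-enumeration oracle for confusion-matrix metrics: expand
# the matrix into (truth, estimate) pairs and count directly
oracle_metrics <- function(cm) {
  k <- nrow(cm)
  pairs <- NULL
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (cm[i, j] > 0) {
        pairs <- rbind(pairs, matrix(rep(c(i, j), cm[i, j]), ncol = 2, byrow = TRUE))
      }
    }
  }
  acc <- sum(pairs[, 1] == pairs[, 2]) / nrow(pairs)
  per_class <- lapply(seq_len(k), function(cls) {
    tp <- sum(pairs[, 1] == cls & pairs[, 2] == cls)
    fp <- sum(pairs[, 1] != cls & pairs[, 2] == cls)
    fn <- sum(pairs[, 1] == cls & pairs[, 2] != cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
  })
  list(accuracy = acc, per_class = do.call(rbind, per_class))
}

random_confusion <- function(k, max_count = 50) {
  matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
}
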