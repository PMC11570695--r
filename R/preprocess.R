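# Three-stage preprocessing chain: RGB -> grayscale, percentile contrast
# stretch (bottom/top 1% saturated), resize to the fixed classifier input.
# Every stage is deterministic, bounds-preserving, and re-quantises to
# 8-bit integers (round half away from zero).

#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luma: `round(0.299 R + 0.587 G + 0.114 B)` per pixel.
#'
#' @param img Integer array `H x W x 3` with values in `[0, 255]`.
#' @param weights Channel weights (must sum to 1).
#' @return An `H x W` integer matrix in `[0, 255]`.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    abort("`img` must be an H x W x 3 RGB array.")
  }
  if (length(weights) != 3 || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be 3 values summing to 1.")
  }
  gray <- round_half_up(
    weights[1] * img[, , 1] + weights[2] * img[, , 2] + weights[3] * img[, , 3]
  )
  storage.mode(gray) <- "integer"
  gray
}

#' Percentile contrast stretch
#'
#' Saturates the bottom `low_tail` and top `high_tail` fractions of pixel
#' values and maps the remaining range linearly onto `[0, 255]`. Quantiles
#' are the linear-interpolation quantiles of the pixel multiset
#' ([stats::quantile()] type 7), computed per image. Pixels at or below the
#' low quantile become 0, those at or above the high quantile become 255.
#'
#' A constant (degenerate) image is returned unchanged with a warning,
#' keeping pipelines robust to blank frames.
#'
#' @param img Grayscale integer matrix in `[0, 255]`.
#' @param low_tail,high_tail Saturated tail fractions; both >= 0 and
#'   summing to < 1. Defaults saturate 1% at each end.
#' @return Stretched image, same shape, integer `[0, 255]`.
#' @export
stretch_contrast <- function(img, low_tail = 0.01, high_tail = 0.01) {
  if (low_tail < 0 || high_tail < 0 || low_tail + high_tail >= 1) {
    abort("Tails must be >= 0 and sum to < 1.")
  }
  q <- quantile(img, c(low_tail, 1 - high_tail), type = 7, names = FALSE)
  if (q[1] >= q[2]) {
    warn("Degenerate intensity range; image returned unchanged.")
    return(img)
  }
  out <- round_half_up((pmin(pmax(img, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * 255)
  storage.mode(out) <- "integer"
  out
}

bilinear_weights <- function(n_src, n_dst) {
  # half-pixel-centre alignment; rows of the returned matrix are convex
  # weights over source positions
  s <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
  s <- pmin(pmax(s, 0), n_src - 1)
  i0 <- pmin(floor(s), n_src - 1)
  f <- s - i0
  i1 <- pmin(i0 + 1, n_src - 1)
  w <- matrix(0, n_dst, n_src)
  w[cbind(seq_len(n_dst), i0 + 1)] <- 1 - f
  w[cbind(seq_len(n_dst), i1 + 1)] <- w[cbind(seq_len(n_dst), i1 + 1)] + f
  w
}

nearest_weights <- function(n_src, n_dst) {
  s <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
  i <- pmin(pmax(round_half_up(s), 0), n_src - 1)
  w <- matrix(0, n_dst, n_src)
  w[cbind(seq_len(n_dst), i + 1)] <- 1
  w
}

#' Resize a grayscale image to the classifier input size
#'
#' Separable interpolation with half-pixel-centre alignment; bilinear by
#' default (nearest-neighbour available for ablation). An input already at
#' the target size passes through pixel-identically, and constant images
#' stay constant.
#'
#' @param img Grayscale integer matrix, at least 2 x 2.
#' @param size Target `(height, width)`; default the 100 x 100 classifier
#'   input.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Integer matrix of the target size in `[0, 255]`.
#' @export
resize_to_input <- function(img, size = c(100, 100),
                            method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(img)) || any(dim(img) < 2)) {
    abort("`img` must be a matrix of at least 2 x 2 pixels.")
  }
  if (any(size < 1)) abort("Target size must be positive.")
  wfun <- if (method == "bilinear") bilinear_weights else nearest_weights
  wy <- wfun(nrow(img), size[1])
  wx <- wfun(ncol(img), size[2])
  out <- clamp8(round_half_up(wy %*% img %*% t(wx)))
  storage.mode(out) <- "integer"
  out
}

#' Full preprocessing chain
#'
#' Composition `to_grayscale()` then `stretch_contrast()` then
#' `resize_to_input()`, in that order (stretch before resize: saturation
#' quantiles are estimated on the full-resolution pixel multiset).
#'
#' @param img RGB integer array `H x W x 3` (a grayscale matrix is
#'   accepted and skips conversion).
#' @inheritParams stretch_contrast
#' @inheritParams resize_to_input
#' @return Integer matrix of the target size in `[0, 255]`.
#' @export
preprocess <- function(img, low_tail = 0.01, high_tail = 0.01,
                       size = c(100, 100), method = "bilinear") {
  gray <- if (length(dim(img)) == 3) to_grayscale(img) else img
  resize_to_input(
    stretch_contrast(gray, low_tail = low_tail, high_tail = high_tail),
    size = size, method = method
  )
}

#' Preprocess every image of a loaded dataset
#'
#' Maps [preprocess()] over the `image` list-column of a dataset tibble
#' (as returned by [load_dataset()]).
#'
#' @param data Dataset tibble with an `image` list-column.
#' @inheritParams preprocess
#' @return The tibble with `image` replaced by processed matrices.
#' @export
preprocess_dataset <- function(data, low_tail = 0.01, high_tail = 0.01,
                               size = c(100, 100), method = "bilinear") {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  dplyr::mutate(data, image = purrr::map(
    .data$image, preprocess,
    low_tail = low_tail, high_tail = high_tail, size = size, method = method
  ))
}

#' Preprocess a folder-per-class image tree on disk
#'
#' Reads every class folder under `in_dir`, preprocesses each PNG and
#' writes the result (grayscale PNG) under `out_dir` with the same layout.
#'
#' @param in_dir,out_dir Dataset roots.
#' @inheritParams preprocess
#' @return Tibble of written paths, invisibly.
#' @export
preprocess_dir <- function(in_dir, out_dir, low_tail = 0.01, high_tail = 0.01,
                           size = c(100, 100), method = "bilinear") {
  data <- load_dataset(in_dir)
  data <- preprocess_dataset(data,
    low_tail = low_tail, high_tail = high_tail,
    size = size, method = method
  )
  rel <- file.path(data$concentration, basename(data$path))
  out <- file.path(out_dir, rel)
  for (d in unique(dirname(out))) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  purrr::walk2(data$image, out, function(img, path) {
    png::writePNG(img / 255, path)
  })
  invisible(tibble(path = out, concentration = data$concentration))
}
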