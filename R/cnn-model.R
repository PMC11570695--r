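# Model surface: architecture specification, closed-form parameter count,
# weight initialisation, forward pass and prediction. The architecture is
# two conv-ReLU-batchnorm blocks, an optional channel-wise
# normalised-exponential (softmax) stage after the conv stack, then
# flatten -> dense (+ dropout) -> dense(classes) -> softmax.

#' Rectifier activation
#'
#' `f(x) = max(0, x)`, applied element-wise after each convolution.
#'
#' @param x Numeric vector or array.
#' @export
relu <- function(x) pmax(x, 0)

#' CNN architecture specification
#'
#' Describes the two-block 2-D CNN. With the defaults (100 x 100 input,
#' 16 then 32 filters with 3 x 3 kernels, stride 1, "same" padding, a
#' 240-unit dense layer and a 16-class head) the closed-form trainable
#' parameter count exceeds 75 million — nearly all of it in the
#' flatten-to-dense weight matrix. Use [cnn_spec_small()] for desk-scale
#' work.
#'
#' @param input_size Classifier input `(height, width)` in pixels.
#' @param conv_filters Filter counts of the two (or more) conv blocks.
#' @param kernel_size Square kernel side, per block (recycled).
#' @param stride Convolution stride, per block (recycled).
#' @param padding `"same"` (zero-pad `floor(k/2)`) or `"valid"`.
#' @param inter_block_softmax Include the channel-wise softmax stage that
#'   further normalises the output of the conv stack.
#' @param dense_units Hidden fully-connected layer widths.
#' @param dropout_rate Dropout fraction on the first dense layer, in
#'   `[0, 1)`.
#' @param classes Number of concentration classes.
#' @param concentrations Concentration value (mg/dL) of each class, used
#'   as the class <-> label mapping; length must equal `classes`.
#' @return An object of class `cnn_spec`.
#' @examples
#' cnn_parameter_count(cnn_spec())
#' @export
cnn_spec <- function(input_size = c(100, 100),
                     conv_filters = c(16, 32),
                     kernel_size = 3,
                     stride = 1,
                     padding = c("same", "valid"),
                     inter_block_softmax = TRUE,
                     dense_units = 240,
                     dropout_rate = 0.5,
                     classes = 16,
                     concentrations = concentration_grid()$value) {
  padding <- match.arg(padding)
  n_blocks <- length(conv_filters)
  if (n_blocks < 1 || any(conv_filters < 1)) {
    abort("`conv_filters` must list at least one positive filter count.")
  }
  kernel_size <- rep_len(as.integer(kernel_size), n_blocks)
  stride <- rep_len(as.integer(stride), n_blocks)
  if (any(kernel_size < 1)) abort("Kernel sizes must be positive.")
  if (any(stride < 1)) abort("Strides must be positive.")
  if (!is_count(classes) || classes < 1) abort("`classes` must be a positive count.")
  if (length(concentrations) != classes) {
    abort("`concentrations` must supply one value per class.")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  if (length(input_size) != 2 || any(input_size < 4)) {
    abort("`input_size` must be (height, width), both >= 4.")
  }
  structure(
    list(
      input_size = as.integer(input_size),
      conv_filters = as.integer(conv_filters),
      kernel_size = kernel_size,
      stride = stride,
      padding = padding,
      inter_block_softmax = inter_block_softmax,
      dense_units = as.integer(dense_units),
      dropout_rate = dropout_rate,
      classes = as.integer(classes),
      concentrations = as.numeric(concentrations)
    ),
    class = "cnn_spec"
  )
}

#' Desk-scale CNN specification
#'
#' Reduced profile (~140 k parameters): 32 x 32 input, 8 then 16 filters
#' with 5 x 5 kernels at stride 2, no inter-block softmax stage, one
#' 128-unit dense layer without dropout (regularisation buys nothing at
#' this scale and slows short training budgets). Intended for tests and
#' fast synthetic-data runs.
#'
#' @param ... Overrides forwarded to [cnn_spec()].
#' @export
cnn_spec_small <- function(...) {
  defaults <- list(
    input_size = c(32, 32),
    conv_filters = c(8, 16),
    kernel_size = 5,
    stride = 2,
    inter_block_softmax = FALSE,
    dense_units = 128,
    dropout_rate = 0
  )
  do.call(cnn_spec, modifyList(defaults, list(...)))
}

spec_pad <- function(spec, block) {
  if (spec$padding == "same") spec$kernel_size[block] %/% 2L else 0L
}

# spatial size after each conv block
spec_spatial <- function(spec) {
  h <- spec$input_size[1]
  w <- spec$input_size[2]
  out <- vector("list", length(spec$conv_filters))
  for (i in seq_along(spec$conv_filters)) {
    p <- spec_pad(spec, i)
    h <- conv_out_dim(h, spec$kernel_size[i], spec$stride[i], p)
    w <- conv_out_dim(w, spec$kernel_size[i], spec$stride[i], p)
    out[[i]] <- c(h, w)
  }
  out
}

#' Closed-form trainable parameter count
#'
#' Sums `(kh*kw*c_in + 1)*c_out` per convolution, `2*c` per batch
#' normalisation, and `(n_in + 1)*n_out` per dense layer. Computed
#' analytically from the specification without allocating any weights.
#'
#' @param spec A [cnn_spec()].
#' @return Total trainable parameter count (numeric scalar).
#' @export
cnn_parameter_count <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  total <- 0
  c_in <- 1
  for (i in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[i]
    total <- total + (spec$kernel_size[i]^2 * c_in + 1) * f + 2 * f
    c_in <- f
  }
  sp <- spec_spatial(spec)
  last <- sp[[length(sp)]]
  n_in <- prod(last) * c_in
  for (u in spec$dense_units) {
    total <- total + (n_in + 1) * u
    n_in <- u
  }
  total + (n_in + 1) * spec$classes
}

#' Build (initialise) the CNN
#'
#' Allocates weights for the given specification: He-normal initialisation
#' for convolution and dense kernels, unit gain / zero shift for batch
#' normalisation. The returned model is untrained.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `glucnn` with elements `spec`, `layers`,
#'   `class_mapping` (tibble `index`, `concentration`), and
#'   `param_count`.
#' @export
build_model <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  layers <- list()
  c_in <- 1L
  withr::with_seed(seed, {
    for (i in seq_along(spec$conv_filters)) {
      f <- spec$conv_filters[i]
      k <- spec$kernel_size[i]
      fan_in <- k^2 * c_in
      layers[[length(layers) + 1]] <- list(
        type = "conv", k = k, stride = spec$stride[i], pad = spec_pad(spec, i),
        W = matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
        b = numeric(f)
      )
      layers[[length(layers) + 1]] <- list(type = "relu")
      layers[[length(layers) + 1]] <- list(
        type = "batchnorm", gamma = rep(1, f), beta = numeric(f),
        running_mean = numeric(f), running_var = rep(1, f), momentum = 0.9
      )
      c_in <- f
    }
    if (spec$inter_block_softmax) {
      layers[[length(layers) + 1]] <- list(type = "channel_softmax")
    }
    layers[[length(layers) + 1]] <- list(type = "flatten")
    sp <- spec_spatial(spec)
    n_in <- prod(sp[[length(sp)]]) * c_in
    for (j in seq_along(spec$dense_units)) {
      u <- spec$dense_units[j]
      layers[[length(layers) + 1]] <- list(
        type = "dense",
        W = matrix(rnorm(n_in * u, sd = sqrt(2 / n_in)), n_in, u),
        b = numeric(u)
      )
      layers[[length(layers) + 1]] <- list(type = "relu")
      if (j == 1 && spec$dropout_rate > 0) {
        layers[[length(layers) + 1]] <- list(
          type = "dropout", rate = spec$dropout_rate
        )
      }
      n_in <- u
    }
    layers[[length(layers) + 1]] <- list(
      type = "dense",
      W = matrix(rnorm(n_in * spec$classes, sd = sqrt(1 / n_in)),
        n_in, spec$classes
      ),
      b = numeric(spec$classes)
    )
  })
  model <- structure(
    list(
      spec = spec,
      layers = layers,
      class_mapping = tibble(
        index = seq_len(spec$classes) - 1L,
        concentration = spec$concentrations
      ),
      param_count = cnn_parameter_count(spec),
      trained = FALSE
    ),
    class = "glucnn"
  )
  model
}

#' Backend-reported trainable parameter total
#'
#' Counts the elements of every allocated trainable array (convolution and
#' dense kernels and biases, batch-norm gains and shifts) in a built
#' model — an independent route to the same number as
#' [cnn_parameter_count()].
#'
#' @param model A `glucnn` model.
#' @export
model_parameter_total <- function(model) {
  stopifnot(inherits(model, "glucnn"))
  sum(vapply(model$layers, function(l) {
    # exact [[ indexing: `$b` would partial-match batch-norm's `beta`
    length(l[["W"]]) + length(l[["b"]]) + length(l[["gamma"]]) + length(l[["beta"]])
  }, numeric(1)))
}

#' @export
print.glucnn <- function(x, ...) {
  cat("<glucnn>", if (x$trained) "(trained)" else "(untrained)", "\n")
  cat(sprintf(
    "  input %d x %d x 1 -> %d classes; %s trainable parameters\n",
    x$spec$input_size[1], x$spec$input_size[2], x$spec$classes,
    format(x$param_count, big.mark = ",")
  ))
  invisible(x)
}

# forward pass over a (h, w, 1, n) batch in [0, 1]
glucnn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(x, l, training),
      relu = relu_forward(x),
      batchnorm = batchnorm_forward(x, l, training),
      channel_softmax = channel_softmax_forward(x),
      flatten = flatten_forward(x),
      dense = dense_forward(x, l),
      dropout = dropout_forward(x, l$rate, training)
    )
    if (l$type == "batchnorm" && training) model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(logits = x, caches = caches, model = model)
}

glucnn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      r <- conv_backward(d, l, caches[[i]])
      d <- r$dx
      grads[[i]] <- r$grads
    } else if (l$type == "relu") {
      d <- relu_backward(d, caches[[i]])
    } else if (l$type == "batchnorm") {
      r <- batchnorm_backward(d, l, caches[[i]])
      d <- r$dx
      grads[[i]] <- r$grads
    } else if (l$type == "channel_softmax") {
      d <- channel_softmax_backward(d, caches[[i]])
    } else if (l$type == "flatten") {
      d <- flatten_backward(d, caches[[i]])
    } else if (l$type == "dense") {
      r <- dense_backward(d, l, caches[[i]])
      d <- r$dx
      grads[[i]] <- r$grads
    } else if (l$type == "dropout") {
      d <- dropout_backward(d, caches[[i]])
    }
  }
  grads
}

# stack a list of processed image matrices into a normalised input batch;
# `stats` (per-pixel training-set mean/sd) standardises feature-wise when
# the model carries them
stack_images <- function(images, input_size, stats = NULL) {
  n <- length(images)
  x <- array(0, c(input_size[1], input_size[2], 1, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!all(dim(img) == input_size)) {
      abort(sprintf(
        "Image %d is %s but the model expects %d x %d.",
        i, paste(dim(img), collapse = " x "), input_size[1], input_size[2]
      ))
    }
    x[, , 1, i] <- if (is.null(stats)) {
      img / 255
    } else {
      (img / 255 - stats$mean) / stats$sd
    }
  }
  x
}

# training-set input normalisation on the [0, 1] scale: per-pixel
# centring (removes the static scene structure shared by every capture)
# and one pooled scale (keeps the relative variance of informative vs
# noise-only pixels intact; a per-pixel scale would inflate pure-noise
# background pixels into a memorisation shortcut)
input_statistics <- function(images, input_size, sd_floor = 1 / 255) {
  x <- stack_images(images, input_size)
  mu <- apply(x, c(1, 2), mean)
  pooled <- sqrt(mean(apply(x, c(1, 2), function(v) stats::var(as.vector(v)))))
  list(mean = mu, sd = max(pooled, sd_floor))
}

#' Predict concentration classes
#'
#' Runs the network in inference mode (dropout disabled, batch
#' normalisation using running statistics); the predicted class is the
#' softmax argmax, with ties broken toward the lowest class index.
#'
#' @param object A trained `glucnn`.
#' @param newdata A processed image matrix, a list of them, or a dataset
#'   tibble with an `image` list-column.
#' @param ... Unused.
#' @return A tibble with `.pred_index` (0-based), `.pred_concentration`
#'   (mg/dL) and one `.prob_<concentration>` column per class.
#' @export
predict.glucnn <- function(object, newdata, ...) {
  images <- if (is.data.frame(newdata)) {
    newdata$image
  } else if (is.list(newdata) && !is.null(dim(newdata[[1]]))) {
    newdata
  } else {
    list(newdata)
  }
  x <- stack_images(images, object$spec$input_size, object$input_stats)
  probs <- softmax_rows(glucnn_forward(object, x, training = FALSE)$logits)
  pred <- apply(probs, 1, which.max) # first maximum = lowest class index
  out <- tibble(
    .pred_index = object$class_mapping$index[pred],
    .pred_concentration = object$class_mapping$concentration[pred]
  )
  colnames(probs) <- paste0(".prob_", object$class_mapping$concentration)
  dplyr::bind_cols(out, as_tibble(probs))
}
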