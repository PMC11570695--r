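# Internal neural-network primitives. Batches travel as arrays
# (height, width, channels, batch); convolution is im2col + GEMM with
# index matrices precomputed per layer, so all heavy lifting is BLAS.
# Scatter-add in the convolution backward loops over kernel offsets only:
# within one kernel offset every output position touches a distinct input
# pixel (stride >= 1), so vectorised accumulation is safe.

conv_out_dim <- function(n, k, stride, pad) {
  (n + 2 * pad - k) %/% stride + 1L
}

conv_index <- function(h, w, c, k, stride, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  oh <- conv_out_dim(h, k, stride, pad)
  ow <- conv_out_dim(w, k, stride, pad)
  if (oh < 1 || ow < 1) abort("Convolution output would be empty.")
  starts_r <- rep(seq(0L, by = stride, length.out = oh), times = ow)
  starts_c <- rep(seq(0L, by = stride, length.out = ow), each = oh)
  start_lin <- starts_r + starts_c * hp
  offs <- as.vector(outer(
    as.vector(outer(0:(k - 1L), (0:(k - 1L)) * hp, "+")),
    (0:(c - 1L)) * hp * wp, "+"
  ))
  list(
    idx = outer(start_lin, offs, "+") + 1L,
    oh = oh, ow = ow, hp = hp, wp = wp
  )
}

conv_forward <- function(x, layer, training = FALSE) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; c <- d[3]; n <- d[4]
  ci <- conv_index(h, w, c, layer$k, layer$stride, layer$pad)
  p <- ci$oh * ci$ow
  if (layer$pad > 0) {
    xp <- array(0, c(ci$hp, ci$wp, c, n))
    xp[layer$pad + seq_len(h), layer$pad + seq_len(w), , ] <- x
  } else {
    xp <- x
  }
  plane <- ci$hp * ci$wp * c
  full_idx <- ci$idx[rep(seq_len(p), n), , drop = FALSE] +
    rep((seq_len(n) - 1L) * plane, each = p)
  x_col <- matrix(xp[full_idx], nrow = n * p)
  out <- x_col %*% layer$W
  out <- out + rep(layer$b, each = n * p)
  f <- ncol(layer$W)
  out <- aperm(array(out, c(ci$oh, ci$ow, n, f)), c(1, 2, 4, 3))
  list(
    out = out,
    cache = list(
      x_col = x_col, full_idx = full_idx, in_dim = d,
      hp = ci$hp, wp = ci$wp, plane = plane, n = n
    )
  )
}

conv_backward <- function(dout, layer, cache) {
  f <- ncol(layer$W)
  dout_mat <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = f)
  grads <- list(
    W = crossprod(cache$x_col, dout_mat),
    b = colSums(dout_mat)
  )
  dx_col <- dout_mat %*% t(layer$W)
  dxp <- numeric(cache$plane * cache$n)
  for (j in seq_len(ncol(dx_col))) {
    pos <- cache$full_idx[, j]
    dxp[pos] <- dxp[pos] + dx_col[, j]
  }
  d <- cache$in_dim
  dxp <- array(dxp, c(cache$hp, cache$wp, d[3], d[4]))
  dx <- if (layer$pad > 0) {
    dxp[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2]), , , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, grads = grads)
}

# channel-last matrix view of a (h, w, c, n) activation
channels_to_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

matrix_to_channels <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

batchnorm_forward <- function(x, layer, training) {
  d <- dim(x)
  xm <- channels_to_matrix(x)
  eps <- 1e-5
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(
    out = matrix_to_channels(ym, d), layer = layer,
    cache = list(xhat = xhat, ivar = ivar, dim = d)
  )
}

batchnorm_backward <- function(dout, layer, cache) {
  dym <- channels_to_matrix(dout)
  xhat <- cache$xhat
  m <- nrow(dym)
  grads <- list(gamma = colSums(dym * xhat), beta = colSums(dym))
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  dxm <- sweep(
    sweep(dxhat, 2, colMeans(dxhat), "-") -
      sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
    2, cache$ivar, "*"
  )
  list(dx = matrix_to_channels(dxm, cache$dim), grads = grads)
}

relu_forward <- function(x) {
  list(out = pmax(x, 0), cache = x > 0)
}

relu_backward <- function(dout, cache) {
  dout * cache
}

# normalised-exponential stage across channels at each spatial location
channel_softmax_forward <- function(x) {
  d <- dim(x)
  xm <- channels_to_matrix(x)
  xm <- xm - apply(xm, 1, max)
  e <- exp(xm)
  pm <- e / rowSums(e)
  list(out = matrix_to_channels(pm, d), cache = list(p = pm, dim = d))
}

channel_softmax_backward <- function(dout, cache) {
  dym <- channels_to_matrix(dout)
  p <- cache$p
  dxm <- p * (dym - rowSums(dym * p))
  matrix_to_channels(dxm, cache$dim)
}

flatten_forward <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, prod(d[1:3]), d[4])), cache = d)
}

flatten_backward <- function(dout, cache) {
  array(t(dout), cache)
}

dense_forward <- function(x, layer) {
  out <- x %*% layer$W
  out <- sweep(out, 2, layer$b, "+")
  list(out = out, cache = x)
}

dense_backward <- function(dout, layer, cache) {
  list(
    dx = dout %*% t(layer$W),
    grads = list(W = crossprod(cache, dout), b = colSums(dout))
  )
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its gradient wrt logits
cross_entropy <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  grad <- p
  grad[cbind(seq_len(n), y)] <- grad[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = grad / n)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(param, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
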