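# Shared numeric helpers. The whole pipeline keeps the 8-bit image contract
# explicit: integer intensities in [0, 255], rounded half away from zero.

#' Round half away from zero
#'
#' Deterministic rounding used after every image-processing stage, avoiding
#' the round-half-to-even behaviour of [base::round()] so that 8-bit results
#' are platform- and value-independent.
#'
#' @param x Numeric vector or array.
#' @return `x` rounded to integers (same shape), half-values moving away
#'   from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 140.75))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

#' Derive a reproducible child seed
#'
#' Mixes a master seed with integer coordinates (class index, condition
#' indices, replicate, stage codes) through a multiplicative congruential
#' step modulo 2^31 - 1. The result depends only on the coordinates, never
#' on iteration order, so any subset of a dataset regenerates identically.
#'
#' @param master Integer master seed.
#' @param ... Integer coordinates identifying the consumer of the seed.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  codes <- c(...)
  s <- (as.double(master) %% 2147483646) + 1
  for (code in codes) {
    s <- (s * 48271 + (as.double(code) + 1) * 8191) %% 2147483647
  }
  as.integer((s %% 2147483645) + 1)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == trunc(x)
}
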