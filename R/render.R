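# Synthetic renderer for one outlet-well capture: a coloured well centred
# on white film, plus the device's dark position markers in the corners.
# The markers matter: they pin the lower tail of the intensity histogram,
# so the later percentile contrast stretch normalises illumination away
# instead of collapsing the two-level well/background scene (which would
# map any well colour onto the same stretched value and erase the
# concentration signal).

scene_masks <- function(size, well_shape, well_radius, marker_frac) {
  h <- size[1]
  w <- size[2]
  r_px <- well_radius * min(h, w)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  well <- switch(well_shape,
    disc = (rows - cy)^2 + (cols - cx)^2 <= r_px^2,
    square = abs(rows - cy) <= r_px & abs(cols - cx) <= r_px,
    abort("`well_shape` must be \"disc\" or \"square\".")
  )
  m <- max(1L, round_half_up(marker_frac * min(h, w)))
  marker <- matrix(FALSE, h, w)
  marker[c(seq_len(m), h - seq_len(m) + 1L), c(seq_len(m), w - seq_len(m) + 1L)] <- TRUE
  marker <- marker & !well
  list(well = well, marker = marker)
}

#' Render one synthetic well image
#'
#' Draws a centred well of the given colour on a white-film background with
#' dark fiducial corner markers, applies per-pixel sensor noise, then the
#' illumination and white-balance gains, and quantises to 8-bit. Identical
#' arguments and seed give a bit-identical image.
#'
#' Noise is added to the scene *before* the gains, mimicking
#' illumination-dependent (photon-like) noise; a consequence is that a pure
#' scalar gain rescales signal and noise together and is removed exactly by
#' percentile contrast stretching downstream.
#'
#' @param rgb Well colour, numeric RGB triple in `[0, 255]` (usually from
#'   [concentration_to_rgb()]).
#' @param size `(height, width)` of the rendered image, each >= 32.
#' @param illumination_gain Scalar brightness multiplier (> 0).
#' @param wb_gains,tint Per-channel multipliers (> 0) for camera white
#'   balance and lighting tint.
#' @param noise_sigma Additive noise scale in intensity units (>= 0).
#' @param background RGB of the white film under neutral illumination.
#' @param well_shape `"disc"` or `"square"`.
#' @param well_radius Well half-extent as a fraction of the shorter image
#'   side, in `(0, 0.5]` (larger wells would not fit the image).
#' @param markers Render the dark corner position markers?
#' @param marker_frac Marker square side as a fraction of the shorter side.
#' @param marker_value Marker intensity (black ink reflectance).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   state.
#' @param masks Precomputed scene masks (internal use: lets a generator
#'   reuse the geometry across many renders).
#' @return An integer array `height x width x 3` with values in `[0, 255]`
#'   and attribute `well_mask` (logical matrix of well pixels).
#' @examples
#' img <- render_well_image(concentration_to_rgb(120), size = c(64, 64), seed = 1)
#' dim(img)
#' @export
render_well_image <- function(rgb,
                              size = c(400, 400),
                              illumination_gain = 1,
                              wb_gains = c(1, 1, 1),
                              tint = c(1, 1, 1),
                              noise_sigma = 0,
                              background = c(230, 228, 226),
                              well_shape = c("disc", "square"),
                              well_radius = 0.3,
                              markers = TRUE,
                              marker_frac = 0.12,
                              marker_value = 8,
                              seed = NULL,
                              masks = NULL) {
  well_shape <- match.arg(well_shape)
  rgb <- unname(as.numeric(rgb))
  if (length(rgb) != 3 || any(rgb < 0) || any(rgb > 255)) {
    abort("`rgb` must be 3 intensities in [0, 255].")
  }
  if (length(size) != 2 || any(size < 32)) {
    abort("`size` must be (height, width) with both >= 32.")
  }
  if (well_radius <= 0 || well_radius > 0.5) {
    abort("`well_radius` must lie in (0, 0.5]: the well must fit the image.")
  }
  if (illumination_gain <= 0 || any(wb_gains <= 0) || any(tint <= 0)) {
    abort("Gains must be strictly positive.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  size <- as.integer(size)
  h <- size[1]
  w <- size[2]

  if (is.null(masks)) {
    masks <- scene_masks(size, well_shape, well_radius, marker_frac)
  }
  scene <- array(rep(background, each = h * w), dim = c(h, w, 3))
  for (k in 1:3) {
    ch <- scene[, , k]
    ch[masks$well] <- rgb[k]
    if (markers) ch[masks$marker] <- marker_value
    scene[, , k] <- ch
  }

  if (noise_sigma > 0) {
    noise_draw <- function() array(rnorm(h * w * 3, sd = noise_sigma), dim = c(h, w, 3))
    noise <- if (is.null(seed)) noise_draw() else withr::with_seed(seed, noise_draw())
    scene <- scene + noise
  }

  gains <- illumination_gain * wb_gains * tint
  # floor(x + 0.5) rounds half away from zero for x >= -0.5; more negative
  # values land below 0 and are clamped anyway
  out <- clamp8(floor(scene * rep(gains, each = h * w) + 0.5))
  storage.mode(out) <- "integer"
  attr(out, "well_mask") <- masks$well
  out
}
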