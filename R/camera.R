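# Capture-condition model: which phone, which lighting, which spot in the
# room. Lighting and location act photometrically as a scalar illumination
# gain plus a per-channel tint; each camera profile carries white-balance
# gains and a sensor noise scale.

#' Smartphone camera profiles
#'
#' The three handset profiles of the capture campaign, with nominal sensor
#' resolution, optics, and the rendering parameters attached to each
#' profile: white-balance gains (dimensionless, per channel) and additive
#' sensor noise scale (8-bit intensity units).
#'
#' Optics (resolution, focal length, aperture) are the published handset
#' values; white-balance gains and noise scales are synthetic rendering
#' defaults since no radiometric calibration of the handsets exists.
#'
#' @return A tibble with one row per camera profile.
#' @examples
#' camera_profiles()
#' @export
camera_profiles <- function() {
  tibble(
    camera = c("iphone_xr", "moto_g62_5g", "pixel_6a"),
    sensor_h = c(3024L, 2296L, 2268L),
    sensor_w = c(4032L, 4080L, 4032L),
    focal_length_mm = c(4, 4, 4),
    aperture_f = c(1.8, 1.8, 1.7),
    gain_r = c(1.00, 1.02, 0.98),
    gain_g = c(1.00, 1.00, 1.00),
    gain_b = c(1.00, 0.97, 1.03),
    noise_sigma = c(3.0, 3.5, 2.5)
  )
}

#' Lighting profiles
#'
#' Photometric model of the two lighting regimes: natural light (fluorescent
#' tubes off) is slightly dimmer and warmer; artificial light (tubes on) is
#' the neutral reference.
#'
#' @return A tibble with per-lighting scalar gain and RGB tint multipliers.
#' @export
lighting_profiles <- function() {
  tibble(
    lighting = c("natural", "artificial"),
    light_gain = c(0.9, 1.0),
    tint_r = c(1.03, 1.00),
    tint_g = c(1.00, 1.00),
    tint_b = c(0.95, 1.00)
  )
}

# Locations perturb the scalar illumination gain by +-10%.
location_gain <- function(location) {
  if (!all(location %in% 1:3)) {
    abort("`location` must be in 1:3.")
  }
  c(0.9, 1.0, 1.1)[location]
}

#' Capture-condition grid
#'
#' Full factorial grid of capture conditions (lighting x location x camera
#' x replicate), with the derived scalar `illumination_gain` =
#' lighting gain x location gain and the per-channel white-balance/tint
#' multipliers used by the renderer.
#'
#' @param lightings Character subset of `lighting_profiles()$lighting`.
#' @param locations Integer locations (1-3).
#' @param cameras A camera-profile tibble, defaulting to [camera_profiles()].
#' @param replicates Number of replicate images per cell.
#' @return A tibble, one row per condition cell.
#' @export
capture_conditions <- function(lightings = lighting_profiles()$lighting,
                               locations = 1:3,
                               cameras = camera_profiles(),
                               replicates = 5) {
  if (length(lightings) == 0 || length(locations) == 0 ||
      nrow(cameras) == 0 || replicates < 1) {
    abort("Every capture factor needs at least one level.")
  }
  lp <- lighting_profiles()
  if (!all(lightings %in% lp$lighting)) {
    abort("Unknown lighting level; see `lighting_profiles()`.")
  }
  grid <- tidyr::expand_grid(
    lighting = lightings,
    location = as.integer(locations),
    camera = cameras$camera,
    replicate = seq_len(replicates)
  )
  grid <- dplyr::left_join(grid, lp, by = "lighting")
  grid <- dplyr::left_join(grid, cameras, by = "camera")
  dplyr::mutate(grid,
    illumination_gain = .data$light_gain * location_gain(.data$location)
  )
}
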