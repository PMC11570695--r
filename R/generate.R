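# Dataset generator: the factorial capture campaign in silico. The default
# configuration mirrors the physical campaign — 16 concentrations x
# 2 lightings x 3 locations x 3 cameras x 5 replicates = 1440 images —
# written in the folder-per-class layout the classifier consumes.

#' Generator configuration
#'
#' Bundles every knob of the synthetic capture campaign. The defaults
#' reproduce the structure of the physical dataset: 16 concentration
#' classes (50-200 mg/dL in steps of 10), two lighting regimes, three
#' room locations, three camera profiles and five replicates, i.e. 1440
#' images.
#'
#' @param concentrations Concentration levels in mg/dL.
#' @param lightings Lighting levels (subset of `lighting_profiles()`).
#' @param locations Integer room locations (1-3).
#' @param cameras Camera-profile tibble ([camera_profiles()] rows).
#' @param replicates Replicate images per factorial cell.
#' @param image_size Rendered `(height, width)` in pixels. Synthetic
#'   rendering uses 400 x 400 rather than native phone resolutions: the
#'   downstream resize to the classifier input makes native scale
#'   irrelevant, while the manifest keeps each profile's nominal sensor
#'   resolution.
#' @param well_shape,well_radius,markers,marker_frac,marker_value Scene
#'   geometry, passed to [render_well_image()].
#' @param color_model An [assay_color_model()].
#' @param noise_scale Multiplier on each camera profile's `noise_sigma`
#'   (set 0 for noise-free renders).
#' @param master_seed Integer master seed; per-image seeds are derived from
#'   it and the image's factorial coordinates via [derive_seed()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(concentrations = concentration_grid()$value,
                             lightings = lighting_profiles()$lighting,
                             locations = 1:3,
                             cameras = camera_profiles(),
                             replicates = 5,
                             image_size = c(400, 400),
                             well_shape = "disc",
                             well_radius = 0.3,
                             markers = TRUE,
                             marker_frac = 0.12,
                             marker_value = 8,
                             color_model = assay_color_model(),
                             noise_scale = 1,
                             master_seed = 1L) {
  if (length(concentrations) == 0) abort("`concentrations` must be non-empty.")
  if (any(concentrations < 0)) abort("Concentrations must be non-negative.")
  if (!is_count(replicates)) abort("`replicates` must be a positive integer.")
  if (noise_scale < 0) abort("`noise_scale` must be >= 0.")
  structure(
    list(
      concentrations = sort(unique(as.numeric(concentrations))),
      lightings = lightings,
      locations = as.integer(locations),
      cameras = cameras,
      replicates = as.integer(replicates),
      image_size = as.integer(image_size),
      well_shape = well_shape,
      well_radius = well_radius,
      markers = markers,
      marker_frac = marker_frac,
      marker_value = marker_value,
      color_model = color_model,
      noise_scale = noise_scale,
      master_seed = as.integer(master_seed)
    ),
    class = "generator_config"
  )
}

#' Small-profile generator configuration
#'
#' Desk-scale variant used for fast end-to-end runs and tests: 16 classes,
#' one camera, two lightings, three locations, two replicates (12 images
#' per class), rendered at 64 x 64 with reduced sensor noise.
#'
#' @param ... Overrides forwarded to [generator_config()].
#' @export
generator_config_small <- function(...) {
  defaults <- list(
    cameras = camera_profiles()[1, ],
    replicates = 2,
    image_size = c(64, 64),
    noise_scale = 1 / 3
  )
  args <- modifyList(defaults, list(...))
  do.call(generator_config, args)
}

#' Generate a synthetic colorimetric dataset
#'
#' Renders one image per factorial cell of the configuration into a
#' folder-per-class layout (`<dir>/<concentration>/<image>.png`) and writes
#' a `manifest.csv` at the root recording every image's capture condition
#' and seed. Regenerating with the same configuration is byte-identical.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if absent).
#' @return The manifest tibble, invisibly; columns `path`, `concentration`,
#'   `class_index`, `lighting`, `location`, `camera`, `replicate`, `seed`,
#'   `sensor_h`, `sensor_w`.
#' @export
generate_dataset <- function(config = generator_config(), dir) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(dir)) abort("`dir` is required.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create output directory '%s'.", dir))

  conditions <- capture_conditions(
    lightings = config$lightings,
    locations = config$locations,
    cameras = config$cameras,
    replicates = config$replicates
  )
  cells <- tidyr::expand_grid(
    concentration = config$concentrations,
    conditions
  )
  cells$class_index <- match(cells$concentration, config$concentrations) - 1L
  # per-image seeds derive from condition *values* (not positions in the
  # configured factor lists), so any subset of the design regenerates the
  # same images as the full campaign
  camera_code <- vapply(cells$camera, function(s) sum(utf8ToInt(s)), numeric(1))
  cells$seed <- purrr::pmap_int(
    list(
      cells$concentration,
      match(cells$lighting, lighting_profiles()$lighting),
      cells$location,
      camera_code,
      cells$replicate
    ),
    function(conc, li, loc, cam, rep) {
      derive_seed(config$master_seed, conc, li, loc, cam, rep)
    }
  )
  cells$path <- file.path(
    dir,
    cells$concentration,
    sprintf(
      "%s_%s_loc%d_rep%d.png",
      cells$camera, cells$lighting, cells$location, cells$replicate
    )
  )

  for (d in file.path(dir, unique(cells$concentration))) {
    dir.create(d, showWarnings = FALSE)
  }

  rgb_by_class <- concentration_to_rgb(config$concentrations, config$color_model)
  if (is.null(dim(rgb_by_class))) rgb_by_class <- matrix(rgb_by_class, nrow = 1)
  masks <- scene_masks(
    config$image_size, config$well_shape, config$well_radius, config$marker_frac
  )

  purrr::pwalk(
    list(
      cells$path, match(cells$concentration, config$concentrations),
      cells$illumination_gain, cells$gain_r, cells$gain_g, cells$gain_b,
      cells$tint_r, cells$tint_g, cells$tint_b, cells$noise_sigma, cells$seed
    ),
    function(path, conc_pos, illum, gr, gg, gb, tr, tg, tb, sigma, seed) {
      img <- render_well_image(
        rgb = rgb_by_class[conc_pos, ],
        size = config$image_size,
        illumination_gain = illum,
        wb_gains = c(gr, gg, gb),
        tint = c(tr, tg, tb),
        noise_sigma = sigma * config$noise_scale,
        well_shape = config$well_shape,
        well_radius = config$well_radius,
        markers = config$markers,
        marker_frac = config$marker_frac,
        marker_value = config$marker_value,
        seed = seed,
        masks = masks
      )
      png::writePNG(img / 255, path)
    }
  )

  manifest <- dplyr::select(
    cells,
    "path", "concentration", "class_index", "lighting", "location",
    "camera", "replicate", "seed", "sensor_h", "sensor_w"
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  inform(sprintf(
    "Generated %d images across %d class folders under '%s'.",
    nrow(manifest), length(unique(manifest$concentration)), dir
  ))
  invisible(manifest)
}
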