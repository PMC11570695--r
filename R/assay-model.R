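# Colour physics of the GOD/POD reaction product. Glucose oxidation yields
# H2O2, which couples 4-aminoantipyrine with phenol into a pink quinonimine
# complex; its absorbance grows linearly with glucose concentration. A
# per-channel Beer-Lambert transmittance model turns that into RGB well
# colours: the pink complex absorbs green most strongly, blue moderately,
# red hardly at all.

#' Assay colour model
#'
#' Beer-Lambert colour model for the quinonimine complex. Each channel k of
#' the well colour is `background_k * 10^(-absorptivity_k * path_scale * c)`
#' for concentration `c` in mg/dL, so absorbance is directly proportional to
#' concentration and green intensity decays fastest (pink product).
#'
#' The default green absorptivity (2.65e-3 per mg/dL) makes the green
#' channel fall from 168 at 50 mg/dL to 67 at 200 mg/dL on a background of
#' 228 — about 60% of the usable range below the 50 mg/dL value — keeping
#' adjacent classes separated by 5-8 intensity units: distinguishable, but
#' not trivially so once capture noise is added.
#'
#' @param background RGB background (white film) intensities, length 3,
#'   each in `[0, 255]`. The default (~230) leaves exposure headroom: even
#'   the brightest lighting/location combination (gain 1.1) stays below
#'   the 8-bit ceiling, as a camera's auto-exposure would ensure.
#' @param absorptivity Per-channel absorbance coefficients in 1/(mg/dL);
#'   non-negative, with the green coefficient at least as large as red and
#'   blue.
#' @param path_scale Dimensionless optical path-length multiplier.
#' @return An object of class `assay_color_model`.
#' @examples
#' m <- assay_color_model()
#' concentration_to_rgb(c(50, 100, 200), m)
#' @export
assay_color_model <- function(background = c(230, 228, 226),
                              absorptivity = c(r = 4e-4, g = 2.65e-3, b = 1.2e-3),
                              path_scale = 1) {
  background <- unname(as.numeric(background))
  absorptivity <- unname(as.numeric(absorptivity))
  if (length(background) != 3 || any(background < 0) || any(background > 255)) {
    abort("`background` must be 3 channel intensities in [0, 255].")
  }
  if (length(absorptivity) != 3 || any(absorptivity < 0)) {
    abort("`absorptivity` must be 3 non-negative coefficients.")
  }
  if (absorptivity[2] < absorptivity[1] || absorptivity[2] < absorptivity[3]) {
    abort(paste(
      "Green absorptivity must be the largest channel coefficient:",
      "the quinonimine complex is pink, so green light is absorbed most."
    ))
  }
  if (!is.numeric(path_scale) || length(path_scale) != 1 || path_scale < 0) {
    abort("`path_scale` must be a single non-negative number.")
  }
  structure(
    list(
      background = background,
      absorptivity = absorptivity,
      path_scale = path_scale
    ),
    class = "assay_color_model"
  )
}

#' @export
print.assay_color_model <- function(x, ...) {
  cat("<assay_color_model>\n")
  cat(sprintf("  background RGB : %s\n", paste(x$background, collapse = ", ")))
  cat(sprintf(
    "  absorptivity   : R %.2e, G %.2e, B %.2e per mg/dL\n",
    x$absorptivity[1], x$absorptivity[2], x$absorptivity[3]
  ))
  cat(sprintf("  path scale     : %g\n", x$path_scale))
  invisible(x)
}

#' Well colour at a glucose concentration
#'
#' Applies the Beer-Lambert transmittance model channel-wise:
#' `round(background_k * 10^(-absorptivity_k * path_scale * c))`, clamped to
#' `[0, 255]`. Vectorised over `concentration`.
#'
#' @param concentration Glucose concentrations in mg/dL (non-negative; 0 is
#'   the hypothetical blank and returns the background colour).
#' @param model An [assay_color_model()].
#' @return For a single concentration, a named numeric RGB triple; for
#'   several, a matrix with one row per concentration and columns r, g, b.
#' @export
concentration_to_rgb <- function(concentration, model = assay_color_model()) {
  if (!inherits(model, "assay_color_model")) {
    abort("`model` must be an `assay_color_model`.")
  }
  if (!is.numeric(concentration) || any(!is.finite(concentration))) {
    abort("`concentration` must be finite numeric.")
  }
  if (any(concentration < 0)) {
    abort("Negative glucose concentrations are not physical.")
  }
  absorbance <- outer(concentration, model$absorptivity * model$path_scale)
  rgb <- clamp8(round_half_up(
    rep(model$background, each = length(concentration)) * 10^(-absorbance)
  ))
  if (length(concentration) == 1) {
    setNames(as.numeric(rgb), c("r", "g", "b"))
  } else {
    dimnames(rgb) <- list(NULL, c("r", "g", "b"))
    rgb
  }
}
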