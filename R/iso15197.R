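# ISO 15197-style accuracy bands for blood-glucose monitors: a prediction
# is acceptable within +-15 mg/dL of the reference when the reference is
# below 100 mg/dL, and within +-15% at or above 100 mg/dL. The two rules
# coincide at exactly 100 mg/dL (0.15 * 100 = 15), so the band is
# continuous at the threshold. Boundaries are inclusive.

#' ISO 15197 band check
#'
#' @param true Reference glucose concentrations, mg/dL (positive).
#' @param predicted Predicted concentrations, mg/dL (positive).
#' @param absolute_band Absolute tolerance below the threshold (mg/dL).
#' @param relative_band Relative tolerance at/above the threshold.
#' @param threshold Reference concentration (mg/dL) at which the relative
#'   rule takes over (inclusive).
#' @return Logical vector: prediction within the band.
#' @examples
#' iso15197_within(c(90, 100, 200), c(104, 115, 235))
#' @export
iso15197_within <- function(true, predicted,
                            absolute_band = 15, relative_band = 0.15,
                            threshold = 100) {
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have equal length.")
  }
  if (any(true <= 0) || any(predicted <= 0)) {
    abort("Glucose concentrations must be positive.")
  }
  err <- abs(predicted - true)
  ifelse(true < threshold, err <= absolute_band, err <= relative_band * true)
}

identity_r2 <- function(true, predicted) {
  if (length(true) < 2 || length(unique(true)) < 2) {
    return(NA_real_)
  }
  1 - sum((predicted - true)^2) / sum((true - mean(true))^2)
}

fitted_r2 <- function(true, predicted) {
  if (length(true) < 2 || length(unique(true)) < 2) {
    return(NA_real_)
  }
  summary(stats::lm(predicted ~ true))$r.squared
}

#' ISO 15197 compliance report
#'
#' Flags every (reference, predicted) pair against the ISO band, reports
#' the compliance fraction and whether it reaches the 95% requirement, and
#' computes range-stratified coefficients of determination: `r2_low` over
#' pairs with reference below the threshold and `r2_high` at or above it.
#'
#' R-squared is measured against the identity line by default,
#' `1 - sum((pred - true)^2) / sum((true - mean(true))^2)`, matching the
#' band framing (how far predictions sit from the reference itself); set
#' `r2_method = "fitted"` for the R-squared of a refitted regression
#' line. A stratum with fewer than two distinct reference values has no
#' defined R-squared and reports `NA`.
#'
#' @param true,predicted Concentration pairs in mg/dL, or a data frame
#'   with columns `truth`/`true` and `estimate`/`predicted` as the first
#'   argument.
#' @inheritParams iso15197_within
#' @param r2_method `"identity"` (default) or `"fitted"`.
#' @param pass_fraction Required compliance fraction (0.95 per the
#'   standard).
#' @return An object of class `iso_report`: list with `pairs` (tibble
#'   `true`, `predicted`, `within`), `compliance_fraction`, `pass`,
#'   `r2_low`, `r2_high` and the band parameters.
#' @examples
#' compliance_report(c(50, 60, 70, 80, 90), c(50, 70, 70, 80, 80))
#' @export
compliance_report <- function(true, predicted = NULL,
                              absolute_band = 15, relative_band = 0.15,
                              threshold = 100,
                              r2_method = c("identity", "fitted"),
                              pass_fraction = 0.95) {
  r2_method <- match.arg(r2_method)
  if (is.data.frame(true)) {
    df <- true
    tcol <- intersect(c("truth", "true"), names(df))[1]
    pcol <- intersect(c("estimate", "predicted"), names(df))[1]
    if (is.na(tcol) || is.na(pcol)) {
      abort("Data frame input needs truth/true and estimate/predicted columns.")
    }
    predicted <- df[[pcol]]
    true <- df[[tcol]]
  }
  if (length(true) == 0) abort("At least one (true, predicted) pair is required.")
  within <- iso15197_within(true, predicted,
    absolute_band = absolute_band,
    relative_band = relative_band, threshold = threshold
  )
  r2 <- if (r2_method == "identity") identity_r2 else fitted_r2
  low <- true < threshold
  structure(
    list(
      pairs = tibble(true = true, predicted = predicted, within = within),
      compliance_fraction = mean(within),
      pass = mean(within) >= pass_fraction,
      r2_low = r2(true[low], predicted[low]),
      r2_high = r2(true[!low], predicted[!low]),
      absolute_band = absolute_band,
      relative_band = relative_band,
      threshold = threshold,
      r2_method = r2_method
    ),
    class = "iso_report"
  )
}

#' @export
print.iso_report <- function(x, ...) {
  cat(sprintf(
    "<iso_report> %d pairs | compliance %.1f%% (%s) | R2 low %s, high %s\n",
    nrow(x$pairs), 100 * x$compliance_fraction,
    if (x$pass) "PASS" else "FAIL",
    ifelse(is.na(x$r2_low), "-", sprintf("%.4f", x$r2_low)),
    ifelse(is.na(x$r2_high), "-", sprintf("%.4f", x$r2_high))
  ))
  invisible(x)
}
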