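# The assay's concentration ladder: 16 glucose standards, 50-200 mg/dL in
# 10 mg/dL steps. The ladder doubles as class alphabet (index 0-15) and as
# the numeric target used for ISO band checks.

#' Glucose concentration grid
#'
#' The standard series of glucose concentrations used throughout the
#' pipeline, as a tibble mapping each concentration (mg/dL) to its
#' zero-based class index. With the defaults this is the 16-level ladder
#' 50, 60, ..., 200 mg/dL.
#'
#' @param from,to,by Arithmetic series parameters in mg/dL.
#' @return A tibble with columns `value` (mg/dL) and `index` (0-based).
#' @examples
#' concentration_grid()
#' @export
concentration_grid <- function(from = 50, to = 200, by = 10) {
  if (by <= 0 || to < from) {
    abort("`concentration_grid()` needs `by > 0` and `to >= from`.")
  }
  value <- seq(from, to, by = by)
  tibble(value = value, index = seq_along(value) - 1L)
}

#' Map concentrations to class indices (and back)
#'
#' @param value Concentrations in mg/dL; must belong to the grid.
#' @param grid A tibble from [concentration_grid()].
#' @return `concentration_index()`: 0-based integer indices.
#'   `index_concentration()`: concentrations in mg/dL.
#' @export
concentration_index <- function(value, grid = concentration_grid()) {
  pos <- match(value, grid$value)
  if (anyNA(pos)) {
    bad <- unique(value[is.na(pos)])
    abort(sprintf(
      "Concentration(s) not on the grid: %s",
      paste(bad, collapse = ", ")
    ))
  }
  grid$index[pos]
}

#' @rdname concentration_index
#' @param index 0-based class indices.
#' @export
index_concentration <- function(index, grid = concentration_grid()) {
  pos <- match(index, grid$index)
  if (anyNA(pos)) {
    abort("Class index out of range for the concentration grid.")
  }
  grid$value[pos]
}
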