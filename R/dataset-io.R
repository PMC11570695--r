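# Folder-per-class dataset reader: `<root>/<concentration>/<image>.png`,
# where each folder name is the glucose concentration in mg/dL.

read_image_255 <- function(path) {
  px <- png::readPNG(path)
  px <- round_half_up(px * 255)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3] # drop alpha
  storage.mode(px) <- "integer"
  px
}

#' Load a folder-per-class image dataset
#'
#' Reads every PNG under numeric class folders, labelling each image with
#' its folder's concentration. Files are ordered lexicographically by
#' path, so loading is deterministic. Unreadable files are skipped with a
#' warning; a folder name that does not parse as a concentration (or,
#' when `concentrations` is given, is not in the configured set) is an
#' error naming the folder.
#'
#' @param root Dataset root directory.
#' @param concentrations Optional configured concentration set to validate
#'   folder names against.
#' @return A tibble with columns `path`, `concentration`, `class_index`
#'   and `image` (list of integer arrays/matrices in `[0, 255]`).
#' @export
load_dataset <- function(root, concentrations = NULL) {
  if (!dir.exists(root)) abort(sprintf("Dataset root '%s' does not exist.", root))
  folders <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (length(folders) == 0) abort("No class folders found.")
  conc <- suppressWarnings(as.numeric(folders))
  if (anyNA(conc)) {
    abort(sprintf(
      "Folder name(s) not parseable as a concentration: %s",
      paste(folders[is.na(conc)], collapse = ", ")
    ))
  }
  if (!is.null(concentrations) && !all(conc %in% concentrations)) {
    abort(sprintf(
      "Folder(s) outside the configured concentration set: %s",
      paste(folders[!conc %in% concentrations], collapse = ", ")
    ))
  }
  ord <- order(conc)
  folders <- folders[ord]
  conc <- conc[ord]
  levels <- sort(unique(conc))

  records <- purrr::map2(folders, conc, function(folder, value) {
    paths <- sort(list.files(file.path(root, folder),
      pattern = "\\.png$", full.names = TRUE
    ), method = "radix")
    images <- vector("list", length(paths))
    keep <- logical(length(paths))
    for (i in seq_along(paths)) {
      img <- tryCatch(read_image_255(paths[i]), error = function(e) NULL)
      if (is.null(img)) {
        warn(sprintf("Skipping unreadable image '%s'.", paths[i]))
      } else {
        images[[i]] <- img
        keep[i] <- TRUE
      }
    }
    tibble(
      path = paths[keep],
      concentration = value,
      class_index = match(value, levels) - 1L,
      image = images[keep]
    )
  })
  data <- dplyr::bind_rows(records)
  counts <- table(data$concentration)
  inform(sprintf(
    "Loaded %d images across %d classes (%s per class).",
    nrow(data), length(counts),
    paste(range(counts), collapse = "-")
  ))
  data
}
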