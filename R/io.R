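# On-disk formats and their in-memory counterparts.
#
# All coordinates are micrometers with the image convention: origin top-left,
# y increasing downward. Label raster codes: 0 = background/debris,
# 1 = epithelium, 2 = stroma.

TISSUE_CLASSES <- c(background = 0L, epithelium = 1L, stroma = 2L)
REGION_LABELS <- c("malignant", "non_malignant")

#' Construct a tissue-class label map
#'
#' @param labels Integer matrix; rows are image rows (y), columns are image
#'   columns (x). Values must be 0 (background/debris), 1 (epithelium) or
#'   2 (stroma).
#' @param pixel_size_um Physical pixel size in micrometers (e.g. 0.5 for a
#'   20x scan).
#' @param origin_um Physical position of the raster's top-left corner.
#' @return An object of class `tissue_map`.
#' @export
tissue_map <- function(labels, pixel_size_um, origin_um = c(0, 0)) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  bad <- setdiff(unique(as.integer(labels)), TISSUE_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("label raster contains out-of-range values: %s",
                  paste(sort(bad), collapse = ", ")))
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         origin_um = as.numeric(origin_um)),
    class = "tissue_map"
  )
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf(
    "<tissue_map> %d x %d px at %.3g um/px (%.3g x %.3g um); epithelium %.1f%%, stroma %.1f%%\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size_um,
    ncol(x$labels) * x$pixel_size_um, nrow(x$labels) * x$pixel_size_um,
    100 * mean(x$labels == 1L), 100 * mean(x$labels == 2L)))
  invisible(x)
}

#' Construct a region annotation table
#'
#' @param rings A list of numeric matrices with two columns (x_um, y_um), one
#'   matrix per closed polygon ring. Rings may be given open (first vertex not
#'   repeated); they are treated as closed.
#' @param label Region label, one of `"malignant"` or `"non_malignant"`;
#'   recycled across rings.
#' @return A tibble with columns `label` and `ring` (list column), one row per
#'   polygon ring.
#' @export
region_annotation <- function(rings, label) {
  if (is.matrix(rings)) rings <- list(rings)
  label <- rep_len(label, length(rings))
  ann <- tibble(label = as.character(label), ring = lapply(rings, as.matrix))
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (!is.data.frame(ann) || !all(c("label", "ring") %in% names(ann))) {
    abort("annotation must be a data frame with columns `label` and `ring`.")
  }
  bad <- setdiff(unique(ann$label), REGION_LABELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
  }
  ann$ring <- lapply(ann$ring, function(rg) {
    rg <- as.matrix(rg)
    if (ncol(rg) != 2 || nrow(rg) < 3 || any(!is.finite(rg))) {
      abort("each ring must be a finite numeric matrix with 2 columns and >= 3 vertices.")
    }
    # drop an explicit closing vertex; geometry treats rings as closed
    if (all(rg[1, ] == rg[nrow(rg), ])) rg <- rg[-nrow(rg), , drop = FALSE]
    if (nrow(rg) < 3) abort("ring degenerate after closing.")
    if (abs(polygon_area(rg)) <= 0) abort("ring has zero area.")
    rg
  })
  as_tibble(ann)
}

# shoelace; positive for counterclockwise in a y-down frame is negative, so
# return the absolute value where only magnitude matters
polygon_area <- function(ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Total annotated area
#'
#' @param annotation A region annotation tibble.
#' @param label Optional region label filter.
#' @return Area in square micrometers (sum of absolute ring areas).
#' @export
annotation_area_um2 <- function(annotation, label = NULL) {
  annotation <- validate_annotation(annotation)
  if (!is.null(label)) annotation <- annotation[annotation$label == label, ]
  sum(vapply(annotation$ring, function(rg) abs(polygon_area(rg)), numeric(1)))
}

validate_cells <- function(cells) {
  if (!is.data.frame(cells)) abort("`cells` must be a data frame.")
  needed <- c("x_um", "y_um", "cd8_positive")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cells) > 0 && any(!is.finite(cells$x_um) | !is.finite(cells$y_um))) {
    bad <- which(!is.finite(cells$x_um) | !is.finite(cells$y_um))[1]
    abort(sprintf("non-finite cell coordinate at row %d", bad))
  }
  as_tibble(cells)
}

#' Read a cell table
#'
#' Expects a CSV with header columns `x_um`, `y_um`, `cd8` (0/1).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `x_um`, `y_um`, `cd8_positive` (logical).
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  needed <- c("x_um", "y_um", "cd8")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um) | !(df$cd8 %in% c(0, 1)))
  if (length(bad) > 0) {
    abort(sprintf("unparseable cell record at row %d of %s", bad[1], path))
  }
  tibble(x_um = df$x_um, y_um = df$y_um, cd8_positive = df$cd8 == 1)
}

#' Write a cell table
#'
#' @param cells A cell tibble (`x_um`, `y_um`, `cd8_positive`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  cells <- validate_cells(cells)
  readr::write_csv(
    tibble(x_um = round(cells$x_um, 3), y_um = round(cells$y_um, 3),
           cd8 = as.integer(cells$cd8_positive)),
    path)
  invisible(path)
}

#' Read a tissue-class label raster
#'
#' Reads a single-channel 8-bit PNG whose pixel values are the class codes
#' 0 (background), 1 (epithelium), 2 (stroma).
#'
#' @param path Path to the PNG file.
#' @param pixel_size_um Physical pixel size in micrometers.
#' @param origin_um Physical position of the top-left corner.
#' @return A [tissue_map()].
#' @export
read_tissue_map <- function(path, pixel_size_um, origin_um = c(0, 0)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  tissue_map(labels, pixel_size_um, origin_um)
}

#' Write a tissue-class label raster
#'
#' @param tissue A [tissue_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(tissue, path) {
  stopifnot(inherits(tissue, "tissue_map"))
  png::writePNG(tissue$labels / 255, path)
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with a `label` property
#' (`malignant` or `non_malignant`); coordinates in micrometers.
#'
#' @param path Path to the GeoJSON file.
#' @return A region annotation tibble (`label`, `ring`).
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort(sprintf("%s is not a GeoJSON FeatureCollection", path))
  rows <- purrr::map(gj$features, function(ft) {
    label <- ft$properties$label
    if (is.null(label)) abort("feature lacks a 'label' property")
    if (!identical(ft$geometry$type, "Polygon")) {
      abort(sprintf("unsupported geometry type '%s'", ft$geometry$type %||% "NULL"))
    }
    rings <- purrr::map(ft$geometry$coordinates, function(rg) {
      m <- do.call(rbind, purrr::map(rg, ~ c(.x[[1]], .x[[2]])))
      m
    })
    tibble(label = as.character(label), ring = rings)
  })
  validate_annotation(list_rbind(rows))
}

#' Write region annotations to GeoJSON
#'
#' @param annotation A region annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  feats <- purrr::map2(annotation$ring, annotation$label, function(rg, lab) {
    closed <- rbind(rg, rg[1, , drop = FALSE])
    coords <- list(purrr::map(seq_len(nrow(closed)),
                              ~ c(round(closed[.x, 1], 3), round(closed[.x, 2], 3))))
    list(type = "Feature",
         properties = list(label = lab),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patient cohort table
#'
#' Expects a CSV with columns `patient_id`, `os_months`, `os_event`,
#' `rfs_months`, `rfs_event`; every additional column is treated as a
#' covariate. Missing covariate values are allowed and kept as `NA`
#' (survival models are complete-case per model).
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per patient.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  needed <- c("patient_id", "os_months", "os_event", "rfs_months", "rfs_event")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column %s", paste(missing_cols, collapse = ", ")))
  }
  for (tm in c("os_months", "rfs_months")) {
    bad <- which(!is.na(df[[tm]]) & df[[tm]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive %s at row %d", tm, bad[1]))
    }
  }
  for (ev in c("os_event", "rfs_event")) {
    if (!all(df[[ev]] %in% c(0, 1, NA))) abort(sprintf("%s must be 0/1", ev))
  }
  as_tibble(df)
}

#' Write a patient cohort table
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
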