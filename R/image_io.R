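#' CT slice container
#'
#' Wraps a 2-D pixel array of Hounsfield units together with its physical
#' pixel spacing. Every analysis function in the package consumes this type;
#' physical quantities (areas, gradients, profile distances) are always
#' derived via the spacing, never from raw pixel counts.
#'
#' @param pixels Numeric matrix of HU values (finite, at least 16 x 16).
#' @param spacing_mm Pixel spacing in mm as `c(row, col)`; a single value is
#'   recycled to both axes. Anisotropic spacing is supported.
#' @param id Opaque slice identifier carried into reports.
#' @return An object of class `ct_image` with fields `pixels`, `spacing`
#'   (named `c(row, col)`, mm) and `id`.
#' @examples
#' img <- ct_image(matrix(0, 32, 32), spacing_mm = 0.7)
#' img
#' @export
ct_image <- function(pixels, spacing_mm = c(1, 1), id = "slice") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("`pixels` must be finite", call. = FALSE)
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(spacing_mm) != 2 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be one or two positive numbers", call. = FALSE)
  }
  structure(
    list(pixels = pixels, spacing = c(row = spacing_mm[1], col = spacing_mm[2]),
         id = as.character(id)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %s: %d x %d px, spacing %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Organ mask container
#'
#' A binary mask congruent with a [ct_image()]. Accepts logical matrices or
#' numeric rasters (any nonzero value is treated as inside the mask, so 0/1
#' and 0/255 encodings both work).
#'
#' @param mask Logical or numeric matrix.
#' @return An object of class `organ_mask` with a logical `mask` field.
#' @export
organ_mask <- function(mask) {
  if (inherits(mask, "organ_mask")) return(mask)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- if (is.logical(mask)) mask else mask != 0
  m[is.na(m)] <- FALSE
  structure(list(mask = m), class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("<organ_mask> %d x %d px, %d inside (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# Coerce organ_mask / matrix to a logical matrix.
as_mask_matrix <- function(mask) {
  organ_mask(mask)$mask
}

#' Physical area of an organ mask
#'
#' Area in cm2 computed from the true-pixel count and the image's pixel
#' spacing. Slices whose segmented area is not strictly greater than
#' 100 cm2 are excluded from quality evaluation downstream.
#'
#' @param mask An [organ_mask()] (or matrix coercible to one).
#' @param image The paired [ct_image()] supplying the pixel spacing.
#' @return Area in cm2.
#' @examples
#' img <- ct_image(matrix(0, 100, 100), spacing_mm = 1)
#' mask <- organ_mask(matrix(TRUE, 100, 100))
#' mask_area_cm2(mask, img)  # 100 cm2
#' @export
mask_area_cm2 <- function(mask, image) {
  m <- as_mask_matrix(mask)
  stopifnot(inherits(image, "ct_image"))
  if (!identical(dim(m), dim(image$pixels))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  sum(m) * image$spacing[["row"]] * image$spacing[["col"]] / 100
}

#' Read a mask raster from PNG
#'
#' Any nonzero pixel (first channel for color PNGs) is inside the mask.
#'
#' @param path PNG file path.
#' @return An [organ_mask()].
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  organ_mask(a != 0)
}

#' Write a mask raster to PNG
#'
#' @param mask An [organ_mask()] or matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Write a per-slice quality report
#'
#' Writes the report tibble as CSV (UTF-8, comma separated, one header row)
#' plus a JSON mirror carrying the same rows and, optionally, the
#' configuration used to produce them. Numeric round-trip through
#' [read_quality_report()] is faithful to well beyond 6 significant digits.
#'
#' @param report Tibble as returned by [evaluate_quality()] or
#'   [compare_reconstructions()].
#' @param path CSV output path; the JSON mirror replaces the extension with
#'   `.json`.
#' @param config Optional configuration list echoed into the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path, config = NULL) {
  stopifnot(is.data.frame(report))
  readr::write_csv(report, path, na = "")
  json_path <- sub("\\.[^.]+$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(rows = report, config = config),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read back a quality report CSV
#'
#' @param path CSV path written by [write_quality_report()].
#' @return A tibble.
#' @export
read_quality_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
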