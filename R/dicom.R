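# Minimal DICOM codec for single-frame CT slices, explicit VR little endian.
#
# Scope is deliberately narrow: the classic CT IOD fields needed to round-trip
# phantom fixtures and to ingest anonymized single-file-per-slice series
# (PixelSpacing, RescaleSlope/Intercept, ImagePositionPatient, 16-bit pixel
# data). Enhanced/multi-frame CT, sequences and compressed transfer syntaxes
# are out of scope and rejected with a clear error.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

# VRs that use the 4-byte length form (2 reserved bytes + uint32 length).
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# Encode one data element. `value` is raw for OW, character for string VRs,
# integer for US.
dcm_element <- function(group, elem, vr, value) {
  payload <- if (is.raw(value)) {
    value
  } else switch(vr,
    US = uint16_raw(value),
    {
      s <- as.character(value)
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      r <- charToRaw(s)
      if (length(r) %% 2 == 1) r <- c(r, pad)
      r
    }
  )
  n <- length(payload)
  header <- c(uint16_raw(group), uint16_raw(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(header, as.raw(c(0, 0)), uint32_raw(n), payload)
  } else {
    if (n > 65534) stop("element too long for short VR form", call. = FALSE)
    c(header, uint16_raw(n), payload)
  }
}

dcm_ds <- function(x) paste(format(x, scientific = FALSE, trim = TRUE), collapse = "\\")

#' Write a CT slice as a single-frame DICOM file
#'
#' Emits an explicit-VR little-endian file with the classic CT IOD fields the
#' package's reader requires: Rows/Columns, PixelSpacing, RescaleSlope and
#' RescaleIntercept, ImagePositionPatient and signed 16-bit pixel data. HU
#' values are rounded to the nearest stored integer under the given rescale.
#'
#' @param image A [ct_image()].
#' @param path Output file path.
#' @param instance_number Integer InstanceNumber tag value.
#' @param position ImagePositionPatient as `c(x, y, z)` in mm; slice ordering
#'   on read uses the z component.
#' @param rescale_slope,rescale_intercept Affine map from stored values to HU
#'   (`HU = stored * slope + intercept`).
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(image, path, instance_number = 1L,
                              position = c(0, 0, 0),
                              rescale_slope = 1, rescale_intercept = -1024) {
  stopifnot(inherits(image, "ct_image"))
  stored <- round((image$pixels - rescale_intercept) / rescale_slope)
  if (any(stored < -32768 | stored > 32767)) {
    stop("stored values exceed int16 range under this rescale", call. = FALSE)
  }
  # pixel data is row-major in DICOM
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", SOP_CT_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", paste0("1.2.826.0.1.3680043.8.498.", instance_number)),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))), meta_body)

  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_CT_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", paste0("1.2.826.0.1.3680043.8.498.", instance_number)),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_element(0x0020, 0x0032, "DS", dcm_ds(position)),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(image$pixels)),
    dcm_element(0x0028, 0x0011, "US", ncol(image$pixels)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_ds(c(image$spacing[["row"]], image$spacing[["col"]]))),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 1L),
    dcm_element(0x0028, 0x1052, "DS", dcm_ds(rescale_intercept)),
    dcm_element(0x0028, 0x1053, "DS", dcm_ds(rescale_slope)),
    dcm_element(0x7fe0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# Parse all top-level elements of an explicit-VR-LE file into a named list of
# list(vr, raw) keyed by "gggg,eeee".
dcm_parse <- function(bytes, path) {
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop(sprintf("%s: not a DICOM file (missing DICM magic)", path), call. = FALSE)
  }
  pos <- 133L
  n <- length(bytes)
  elements <- list()
  while (pos + 7L <= n) {
    group <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2,
                     signed = FALSE, endian = "little")
    elem <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2,
                    signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(sprintf("%s: unsupported encoding (expected explicit VR little endian)", path),
           call. = FALSE)
    }
    if (vr %in% LONG_VRS) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4, endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 8L
    }
    if (len < 0) stop(sprintf("%s: undefined-length elements unsupported", path), call. = FALSE)
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    elements[[dcm_tag_key(group, elem)]] <- list(vr = vr, raw = value)
  }
  elements
}

dcm_string <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  r <- el$raw
  # strip trailing padding (space or NUL)
  while (length(r) > 0 && r[length(r)] %in% as.raw(c(0x00, 0x20))) {
    r <- r[-length(r)]
  }
  rawToChar(r)
}

dcm_numbers <- function(elements, key) {
  s <- dcm_string(elements, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elements, key) {
  el <- elements[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", size = 2, signed = FALSE, endian = "little")
}

require_tag <- function(value, tag_name, path) {
  if (is.null(value) || (is.character(value) && !nzchar(value)) ||
      (is.numeric(value) && length(value) == 0)) {
    stop(sprintf("%s: required DICOM tag %s is missing", path, tag_name), call. = FALSE)
  }
  value
}

#' Read one CT slice from a DICOM file
#'
#' Supports uncompressed explicit-VR little-endian single-frame CT objects.
#' Pixel values are converted to HU via `stored * RescaleSlope +
#' RescaleIntercept`; missing PixelSpacing or rescale tags raise an error
#' naming the tag.
#'
#' @param path DICOM file path.
#' @return A list with `image` (a [ct_image()]) and `meta` (instance number,
#'   slice position, rescale parameters).
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  elements <- dcm_parse(bytes, path)

  ts <- dcm_string(elements, dcm_tag_key(0x0002, 0x0010))
  if (!is.null(ts) && ts != TS_EXPLICIT_LE) {
    stop(sprintf("%s: unsupported transfer syntax %s", path, ts), call. = FALSE)
  }
  rows <- require_tag(dcm_us(elements, dcm_tag_key(0x0028, 0x0010)), "Rows (0028,0010)", path)
  cols <- require_tag(dcm_us(elements, dcm_tag_key(0x0028, 0x0011)), "Columns (0028,0011)", path)
  spacing <- require_tag(dcm_numbers(elements, dcm_tag_key(0x0028, 0x0030)),
                         "PixelSpacing (0028,0030)", path)
  slope <- require_tag(dcm_numbers(elements, dcm_tag_key(0x0028, 0x1053)),
                       "RescaleSlope (0028,1053)", path)
  intercept <- require_tag(dcm_numbers(elements, dcm_tag_key(0x0028, 0x1052)),
                           "RescaleIntercept (0028,1052)", path)
  pix_el <- elements[[dcm_tag_key(0x7fe0, 0x0010)]]
  if (is.null(pix_el)) {
    stop(sprintf("%s: required DICOM tag PixelData (7FE0,0010) is missing", path),
         call. = FALSE)
  }
  signed <- identical(dcm_us(elements, dcm_tag_key(0x0028, 0x0103)), 1L)
  stored <- readBin(pix_el$raw, "integer", size = 2, signed = signed,
                    endian = "little", n = rows * cols)
  if (length(stored) != rows * cols) {
    stop(sprintf("%s: PixelData length does not match Rows x Columns", path), call. = FALSE)
  }
  hu <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE) * slope + intercept

  instance <- suppressWarnings(as.integer(dcm_string(elements, dcm_tag_key(0x0020, 0x0013))))
  position <- dcm_numbers(elements, dcm_tag_key(0x0020, 0x0032))
  id <- tools::file_path_sans_ext(basename(path))
  list(
    image = ct_image(hu, spacing_mm = spacing[1:2], id = id),
    meta = list(instance_number = instance, position = position,
                rescale_slope = slope, rescale_intercept = intercept, path = path)
  )
}

#' Read a directory of single-slice DICOM files as a sorted series
#'
#' Slices are ordered by the z component of ImagePositionPatient when present,
#' falling back to InstanceNumber, then file name. A series whose slices have
#' different pixel grids is rejected.
#'
#' @param path Directory containing one DICOM file per slice (`.dcm` or any
#'   file with the DICM magic).
#' @return A list of `list(image, meta)` entries in slice order.
#' @export
load_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  is_dcm <- vapply(files, function(f) {
    b <- readBin(f, raw(), 132)
    length(b) == 132 && rawToChar(b[129:132]) == "DICM"
  }, logical(1))
  files <- files[is_dcm]
  if (length(files) == 0) stop(sprintf("%s: no DICOM slices found", path), call. = FALSE)
  slices <- lapply(sort(files), read_dicom_slice)

  shapes <- vapply(slices, function(s) paste(dim(s$image$pixels), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1) {
    stop(sprintf("%s: mixed slice shapes in series (%s)", path,
                 paste(unique(shapes), collapse = ", ")), call. = FALSE)
  }
  z <- vapply(slices, function(s) {
    p <- s$meta$position
    if (!is.null(p) && length(p) >= 3 && is.finite(p[3])) p[3] else NA_real_
  }, numeric(1))
  inst <- vapply(slices, function(s) {
    i <- s$meta$instance_number
    if (!is.null(i) && length(i) == 1 && is.finite(i)) as.numeric(i) else NA_real_
  }, numeric(1))
  ord <- if (!anyNA(z)) order(z) else if (!anyNA(inst)) order(inst) else seq_along(slices)
  slices[ord]
}
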