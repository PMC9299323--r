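#' Automated noise level from the homogeneous region
#'
#' Draws `n_rois` square ROIs entirely contained in the homogeneous region
#' \eqn{R_H}, takes the sample standard deviation (denominator N-1) of the HU
#' values in each, and reports their mean as the slice noise level. ROI
#' centers are drawn without replacement from all eligible centers (an
#' eligible center is one whose full ROI square lies inside \eqn{R_H}) using
#' the seeded RNG, so the result is exactly reproducible given the seed. ROIs
#' may overlap; a message is emitted when they do.
#'
#' If fewer than `n_rois` eligible centers exist at the requested ROI size,
#' the size shrinks by 2 px at a time down to a minimum of 5 px; if still
#' infeasible an error `"R_H too fragmented"` is raised.
#'
#' @param image A [ct_image()].
#' @param partition A [partition_regions()] result for this image.
#' @param roi_size_px Requested odd ROI side in pixels (default 21, about
#'   15 mm at 0.7 mm spacing).
#' @param n_rois Number of ROIs (default 5).
#' @param seed Integer RNG seed.
#' @return An object of class `noise_result`: `noise_hu`, per-ROI `roi_sds`,
#'   `roi_centers` (row/col matrix), the `roi_size_px` actually used,
#'   `requested_roi_size_px`, `n_rois` and `seed`.
#' @export
noise_level <- function(image, partition, roi_size_px = 21L, n_rois = 5L, seed = 1L) {
  stopifnot(inherits(image, "ct_image"), inherits(partition, "region_partition"))
  rh <- partition$r_h
  if (!identical(dim(rh), dim(image$pixels))) {
    stop("partition and image shapes differ", call. = FALSE)
  }
  size <- as.integer(roi_size_px)
  stopifnot(size >= 5L, size %% 2L == 1L, n_rois >= 1L)

  eligible <- integer(0)
  while (size >= 5L) {
    # full containment: the ROI box sum equals its area (border clipping in
    # box_sum makes centers too close to the image edge ineligible as well)
    elig_mat <- box_sum(rh * 1, size) == size^2
    eligible <- which(elig_mat)
    if (length(eligible) >= n_rois) break
    size <- size - 2L
  }
  if (length(eligible) < n_rois) stop("R_H too fragmented", call. = FALSE)

  centers_idx <- with_local_seed(seed, eligible[sample.int(length(eligible), n_rois)])
  nr <- nrow(rh)
  rows <- (centers_idx - 1L) %% nr + 1L
  cols <- (centers_idx - 1L) %/% nr + 1L
  h <- size %/% 2L
  sds <- vapply(seq_len(n_rois), function(i) {
    sd(image$pixels[(rows[i] - h):(rows[i] + h), (cols[i] - h):(cols[i] + h)])
  }, numeric(1))

  overlap <- FALSE
  if (n_rois > 1) {
    d <- as.matrix(stats::dist(cbind(rows, cols), method = "maximum"))
    overlap <- any(d[upper.tri(d)] < size)
    if (overlap) message("noise_level: ROIs overlap in R_H")
  }
  structure(
    list(noise_hu = mean(sds), roi_sds = sds,
         roi_centers = cbind(row = rows, col = cols),
         roi_size_px = size, requested_roi_size_px = as.integer(roi_size_px),
         n_rois = as.integer(n_rois), seed = as.integer(seed), overlap = overlap),
    class = "noise_result"
  )
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> %.3f HU (mean of %d ROI SDs, %d px ROIs, seed %d)\n",
              x$noise_hu, x$n_rois, x$roi_size_px, x$seed))
  invisible(x)
}

#' Structure sharpness index
#'
#' The raw SSI is the arithmetic mean of the SCF over the structure-edge
#' region \eqn{R_S}; the calibrated SSI maps it onto the physical edge-slope
#' scale (HU/mm) through the linear calibration `coef_a * ssi_raw + coef_b`.
#' The default coefficients come from a phantom calibration against manual
#' perpendicular-profile slope measurements and are scanner- and
#' protocol-specific; recalibrate with [fit_ssi_calibration()] for other
#' acquisition conditions.
#'
#' @param scf A [compute_scf_map()] result.
#' @param partition A [partition_regions()] result computed from the same map.
#' @param coef_a,coef_b Calibration slope and intercept (defaults 6.1398 and
#'   4.2813).
#' @return An object of class `ssi_result`: `ssi_raw`, `ssi_calibrated`,
#'   `coef_a`, `coef_b`, `n_pixels`, and `flag` (`"empty R_S"` when the
#'   structure region is empty, in which case the values are `NA`).
#' @export
structure_sharpness <- function(scf, partition, coef_a = 6.1398, coef_b = 4.2813) {
  stopifnot(inherits(scf, "scf_map"), inherits(partition, "region_partition"))
  n <- sum(partition$r_s)
  if (n == 0) {
    return(structure(
      list(ssi_raw = NA_real_, ssi_calibrated = NA_real_,
           coef_a = coef_a, coef_b = coef_b, n_pixels = 0L, flag = "empty R_S"),
      class = "ssi_result"
    ))
  }
  ssi_raw <- mean(scf$values[partition$r_s])
  structure(
    list(ssi_raw = ssi_raw, ssi_calibrated = coef_a * ssi_raw + coef_b,
         coef_a = coef_a, coef_b = coef_b, n_pixels = n, flag = NA_character_),
    class = "ssi_result"
  )
}

#' @export
print.ssi_result <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("<ssi_result> flagged: %s\n", x$flag))
  } else {
    cat(sprintf("<ssi_result> raw %.4g, calibrated %.4g HU/mm over %d px\n",
                x$ssi_raw, x$ssi_calibrated, x$n_pixels))
  }
  invisible(x)
}

#' Calibrate SSI against reference edge slopes
#'
#' Ordinary least squares of the manual/oracle edge slope \eqn{\xi} on the
#' raw SSI, as used to anchor the SSI to a physical sharpness scale. Returns
#' the fitted slope (`coef_a`), intercept (`coef_b`) and the Pearson
#' correlation between the two measurements.
#'
#' @param data A data frame with columns `ssi_raw` and `slope`, or a numeric
#'   vector of raw SSI values (then `slope` must be given).
#' @param slope Reference slopes when `data` is a vector.
#' @return An object of class `ssi_calibration` with `coef_a`, `coef_b`,
#'   `pearson_r`, `n` and the underlying `data`. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' fit <- fit_ssi_calibration(data.frame(ssi_raw = 1:5, slope = 2 * (1:5) + 1))
#' glance(fit)
#' @export
fit_ssi_calibration <- function(data, slope = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("ssi_raw", "slope") %in% names(data)))
    x <- data$ssi_raw
    y <- data$slope
  } else {
    x <- as.numeric(data)
    y <- as.numeric(slope)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 calibration pairs", call. = FALSE)
  if (sd(x) == 0) stop("constant predictor: raw SSI does not vary", call. = FALSE)
  fit <- lm(y ~ x)
  structure(
    list(coef_a = unname(coef(fit)[2]), coef_b = unname(coef(fit)[1]),
         pearson_r = cor(x, y), n = length(x),
         data = tibble::tibble(ssi_raw = x, slope = y)),
    class = "ssi_calibration"
  )
}

#' @export
print.ssi_calibration <- function(x, ...) {
  cat(sprintf("<ssi_calibration> slope = %.4f * ssi_raw + %.4f (r = %.3f, n = %d)\n",
              x$coef_a, x$coef_b, x$pearson_r, x$n))
  invisible(x)
}

#' Structure alteration index for a reconstruction pair
#'
#' Quantifies how much a target reconstruction (iterative reconstruction or a
#' denoising model) altered anatomical structure relative to a reference
#' (typically FBP). On the subtraction image \eqn{\Delta I = reference -
#' target}, the SAI is the ratio of the sample standard deviation of
#' \eqn{\Delta I} over the structure-edge region to that over the homogeneous
#' region:
#' \deqn{SAI = \sigma_{R_S} / \sigma_{R_H} |_{\Delta I}.}
#' Uniform noise removal leaves \eqn{\Delta I} statistically identical in both
#' regions (SAI near 1); structure smearing concentrates residuals at edges
#' (SAI above 1); edge-preserving denoising yields SAI below 1.
#'
#' The partition must come from the reference image's SCF map, so one
#' partition is reused for the pair.
#'
#' @param reference,target Congruent [ct_image()] objects on the same grid.
#' @param partition A [partition_regions()] result computed on `reference`.
#' @return An object of class `sai_result`: `sai`, `sigma_rs`, `sigma_rh`,
#'   and `flag` (`"no-op denoiser"` when the images are identical so the
#'   ratio is undefined).
#' @export
structure_alteration <- function(reference, target, partition) {
  stopifnot(inherits(reference, "ct_image"), inherits(target, "ct_image"),
            inherits(partition, "region_partition"))
  if (!identical(dim(reference$pixels), dim(target$pixels))) {
    stop("reference and target shapes differ", call. = FALSE)
  }
  delta <- reference$pixels - target$pixels
  sigma_rh <- if (any(partition$r_h)) sd(delta[partition$r_h]) else NA_real_
  sigma_rs <- if (any(partition$r_s)) sd(delta[partition$r_s]) else NA_real_
  flag <- NA_character_
  sai <- NA_real_
  if (!is.na(sigma_rh) && sigma_rh == 0) {
    flag <- "no-op denoiser"
  } else if (is.finite(sigma_rs) && is.finite(sigma_rh)) {
    sai <- sigma_rs / sigma_rh
  } else {
    flag <- "empty region"
  }
  structure(
    list(sai = sai, sigma_rs = sigma_rs, sigma_rh = sigma_rh, flag = flag),
    class = "sai_result"
  )
}

#' @export
print.sai_result <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("<sai_result> flagged: %s\n", x$flag))
  } else {
    cat(sprintf("<sai_result> SAI %.3f (sigma_RS %.3f / sigma_RH %.3f HU)\n",
                x$sai, x$sigma_rs, x$sigma_rh))
  }
  invisible(x)
}
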