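# broom-style tidiers for the result objects.

#' @export
tidy.ssi_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "ssi_raw"),
    estimate = c(x$coef_b, x$coef_a)
  )
}

#' @export
glance.ssi_calibration <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, r.squared = x$pearson_r^2, n = x$n)
}

#' @export
tidy.noise_result <- function(x, ...) {
  tibble::tibble(
    roi = seq_len(x$n_rois),
    row = x$roi_centers[, "row"],
    col = x$roi_centers[, "col"],
    roi_size_px = x$roi_size_px,
    sd_hu = x$roi_sds
  )
}

#' @export
glance.noise_result <- function(x, ...) {
  tibble::tibble(noise_hu = x$noise_hu, n_rois = x$n_rois,
                 roi_size_px = x$roi_size_px, seed = x$seed, overlap = x$overlap)
}

#' @export
tidy.ssi_result <- function(x, ...) {
  tibble::tibble(ssi_raw = x$ssi_raw, ssi_calibrated = x$ssi_calibrated,
                 coef_a = x$coef_a, coef_b = x$coef_b,
                 n_pixels = x$n_pixels, flag = x$flag)
}

#' @export
tidy.sai_result <- function(x, ...) {
  tibble::tibble(sai = x$sai, sigma_rs = x$sigma_rs, sigma_rh = x$sigma_rh,
                 flag = x$flag)
}

#' @export
tidy.edge_profile_set <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$profiles), function(i) {
    dplyr::mutate(x$profiles[[i]], profile = i, .before = 1)
  }))
}

#' @export
tidy.region_partition <- function(x, ...) {
  rh <- which(x$r_h, arr.ind = TRUE)
  rs <- which(x$r_s, arr.ind = TRUE)
  tibble::tibble(
    row = c(rh[, 1], rs[, 1]),
    col = c(rh[, 2], rs[, 2]),
    region = rep(c("R_H", "R_S"), c(nrow(rh), nrow(rs)))
  )
}
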