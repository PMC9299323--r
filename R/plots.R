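# ggplot2 displays for the main result types.

#' @export
autoplot.scf_map <- function(object, trans = "log1p", ...) {
  d <- matrix_to_tibble(object$values, "scf")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$scf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Structure coherence feature", x = NULL, y = NULL)
}

#' @export
autoplot.region_partition <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(R_H = "#d73027", R_S = "#4575b4")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Homogeneous (R_H) and structure-edge (R_S) regions",
                  x = NULL, y = NULL)
}

#' @export
autoplot.edge_profile_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s_mm, y = .data$hu,
                                  group = .data$profile)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", linewidth = 1, colour = "red") +
    ggplot2::labs(x = "distance along normal (mm)", y = "HU",
                  title = "Perpendicular edge profiles")
}

#' @export
autoplot.ssi_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ssi_raw, y = .data$slope)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$coef_a, intercept = object$coef_b,
                         colour = "red") +
    ggplot2::labs(x = "raw SSI (mean SCF over R_S)",
                  y = "reference edge slope (HU/mm)",
                  title = sprintf("SSI calibration (r = %.3f)", object$pearson_r))
}

#' Bland-Altman plot of two paired measurements
#'
#' @param x,y Paired numeric vectors (e.g. automated vs manual noise levels).
#' @param xlab,ylab Axis annotations for the measurement names.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(x, y, xlab = "measurement 1", ylab = "measurement 2") {
  stats <- agreement_stats(x, y)
  d <- tibble::tibble(mean = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = stats$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(stats$loa_low, stats$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = sprintf("mean of %s and %s", xlab, ylab),
                  y = sprintf("%s - %s", xlab, ylab),
                  title = "Bland-Altman agreement")
}
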