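#' Edge polyline
#'
#' An ordered polyline along a tissue-vessel boundary, in fractional pixel
#' coordinates `(row, col)`. This is the "manually drawn" edge of the
#' reference sharpness measurement; here it is either read from a file or
#' produced as ground truth by the phantom generator.
#'
#' @param vertices Two-column matrix or data frame of `(row, col)` vertices,
#'   at least two, with consecutive vertices distinct.
#' @return An object of class `edge_line` (a two-column matrix).
#' @export
edge_line <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 2) {
    stop("an edge line needs a 2-column (row, col) matrix with >= 2 vertices",
         call. = FALSE)
  }
  storage.mode(v) <- "double"
  colnames(v) <- c("row", "col")
  if (any(rowSums(abs(diff(v))) == 0)) {
    stop("consecutive edge-line vertices must be distinct", call. = FALSE)
  }
  structure(v, class = c("edge_line", "matrix"))
}

#' Read an edge line from a CSV of (row, col) vertices
#'
#' @param path CSV path with columns `row` and `col`.
#' @return An [edge_line()].
#' @export
read_edge_line <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  edge_line(cbind(d$row, d$col))
}

#' Write an edge line to CSV
#' @param line An [edge_line()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_line <- function(line, path) {
  readr::write_csv(tibble::tibble(row = line[, 1], col = line[, 2]), path)
  invisible(path)
}

#' Sample perpendicular intensity profiles along an edge line
#'
#' Profile origins are placed at equal arc length (in mm) along the polyline;
#' at each origin, HU values are sampled by bilinear interpolation at `step_mm`
#' increments from `-half_length_mm` to `+half_length_mm` along the local unit
#' normal (physical coordinates, so anisotropic spacing is handled). The
#' normal at a vertex is the average of the adjacent segment normals. Each
#' profile's orientation is fixed so that it rises: if the mean intensity on
#' the positive side is below the negative side, the profile is reversed.
#' Profiles that would leave the image are dropped with a warning.
#'
#' @param image A [ct_image()].
#' @param line An [edge_line()].
#' @param spacing_along_mm Arc-length spacing of profile origins (default 1).
#' @param half_length_mm Half-length of each profile (default 5).
#' @param step_mm Sample step; defaults to the smaller pixel spacing.
#' @return An object of class `edge_profile_set`: a list of profile tibbles
#'   (`s_mm`, `hu`), the origin coordinates, and `n_dropped`.
#' @export
sample_perpendicular_profiles <- function(image, line, spacing_along_mm = 1,
                                          half_length_mm = 5, step_mm = NULL) {
  stopifnot(inherits(image, "ct_image"), inherits(line, "edge_line"),
            spacing_along_mm > 0, half_length_mm > 0)
  if (is.null(step_mm)) step_mm <- min(image$spacing)
  stopifnot(step_mm > 0)
  sp <- image$spacing

  # physical vertex coordinates (mm)
  phys <- cbind(line[, 1] * sp[["row"]], line[, 2] * sp[["col"]])
  seg <- diff(phys)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  origins_s <- seq(0, total, by = spacing_along_mm)
  if (abs(total - origins_s[length(origins_s)]) > 1e-9 &&
      total - origins_s[length(origins_s)] >= spacing_along_mm - 1e-9) {
    origins_s <- c(origins_s, total)
  }

  unit_normals <- cbind(-seg[, 2], seg[, 1]) / seg_len
  offsets <- seq(-half_length_mm, half_length_mm, by = step_mm)

  profiles <- list()
  origins <- NULL
  n_dropped <- 0L
  eps <- 1e-9
  for (s in origins_s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    t_frac <- (s - cum[i]) / seg_len[i]
    pt <- phys[i, ] + t_frac * seg[i, ]
    # average adjacent normals at interior vertices
    at_vertex <- (t_frac < eps && i > 1L) || (t_frac > 1 - eps && i < nrow(seg))
    nrm <- if (at_vertex) {
      j <- if (t_frac < eps) i - 1L else i + 1L
      v <- unit_normals[i, ] + unit_normals[j, ]
      if (sqrt(sum(v^2)) < eps) unit_normals[i, ] else v / sqrt(sum(v^2))
    } else {
      unit_normals[i, ]
    }
    pr <- pt[1] + offsets * nrm[1]
    pc <- pt[2] + offsets * nrm[2]
    rows <- pr / sp[["row"]]
    cols <- pc / sp[["col"]]
    hu <- bilinear_interp(image$pixels, rows, cols)
    if (anyNA(hu)) {
      n_dropped <- n_dropped + 1L
      next
    }
    if (mean(hu[offsets > 0]) < mean(hu[offsets < 0])) hu <- rev(hu)
    profiles[[length(profiles) + 1L]] <-
      tibble::tibble(s_mm = offsets - offsets[1], hu = hu)
    origins <- rbind(origins, c(row = pt[1] / sp[["row"]], col = pt[2] / sp[["col"]]))
  }
  if (n_dropped > 0) {
    warning(sprintf("%d profile(s) dropped: samples outside the image", n_dropped),
            call. = FALSE)
  }
  if (length(profiles) == 0) stop("no usable profiles along this edge line", call. = FALSE)
  structure(
    list(profiles = profiles, origins = origins, n_dropped = n_dropped,
         half_length_mm = half_length_mm, step_mm = step_mm),
    class = "edge_profile_set"
  )
}

#' Clip a rising profile to its 10-90% intensity span
#'
#' The baseline is the mean of the first quartile of samples (by position
#' along the profile) — a robust stand-in for the profile floor when the HU
#' baseline is far from zero. Thresholds are set at
#' `baseline + 0.10 * (max - baseline)` and `baseline + 0.90 * (max -
#' baseline)`; the clipped profile runs from the first sample at or above the
#' low threshold to the first sample at or above the high threshold. Profiles
#' that are flat, never cross the thresholds in order, or retain fewer than 4
#' samples are dropped (`NULL` is returned).
#'
#' @param profile Tibble with columns `s_mm` and `hu`, rising left to right.
#' @return The clipped tibble, or `NULL` when the profile is unusable.
#' @export
clip_profile_10_90 <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("s_mm", "hu") %in% names(profile)))
  n <- nrow(profile)
  if (n < 8) return(NULL)
  baseline <- mean(profile$hu[seq_len(max(1L, floor(n / 4)))])
  peak <- max(profile$hu)
  rng <- peak - baseline
  if (rng <= 0) return(NULL)
  lo <- baseline + 0.10 * rng
  hi <- baseline + 0.90 * rng
  i_lo <- which(profile$hu >= lo)[1]
  i_hi <- which(profile$hu >= hi)[1]
  if (is.na(i_lo) || is.na(i_hi) || i_hi <= i_lo) return(NULL)
  out <- profile[i_lo:i_hi, ]
  if (nrow(out) < 4) return(NULL)
  out
}

#' Edge-profile slope
#'
#' Ordinary least-squares slope of intensity on distance,
#' \eqn{\xi_l = cov(s_l, I_l) / var(s_l)}, in HU/mm. This is the
#' per-profile sharpness of the manual reference measurement; steeper is
#' sharper.
#'
#' @param profile Tibble with columns `s_mm` and `hu` (normally the output of
#'   [clip_profile_10_90()]).
#' @return Slope in HU/mm.
#' @examples
#' profile_slope(data.frame(s_mm = 0:5, hu = 5 * (0:5) + 3))  # 5
#' @export
profile_slope <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("s_mm", "hu") %in% names(profile)))
  s <- profile$s_mm
  if (length(s) < 2 || var(s) == 0) {
    stop("profile distances are constant; slope undefined", call. = FALSE)
  }
  cov(s, profile$hu) / var(s)
}

#' Mean edge slope of a profile set
#'
#' Clips every profile to its 10-90% rise, computes the per-profile OLS
#' slope, and averages. Profiles the clipping rejects are dropped and counted.
#'
#' @param profile_set An [sample_perpendicular_profiles()] result.
#' @return The set with `slopes`, `mean_slope` and `n_unusable` filled in.
#' @export
measure_edge_slopes <- function(profile_set) {
  stopifnot(inherits(profile_set, "edge_profile_set"))
  clipped <- lapply(profile_set$profiles, clip_profile_10_90)
  keep <- !vapply(clipped, is.null, logical(1))
  slopes <- vapply(clipped[keep], profile_slope, numeric(1))
  if (length(slopes) == 0) stop("no profile survived 10-90% clipping", call. = FALSE)
  profile_set$slopes <- slopes
  profile_set$mean_slope <- mean(slopes)
  profile_set$n_unusable <- sum(!keep)
  profile_set
}

#' One-shot reference sharpness along an edge line
#'
#' Convenience wrapper: sample perpendicular profiles, clip each to its
#' 10-90% rise, regress, and return the mean slope in HU/mm.
#'
#' @inheritParams sample_perpendicular_profiles
#' @return Mean edge slope (HU/mm).
#' @export
edge_slope_reference <- function(image, line, spacing_along_mm = 1,
                                 half_length_mm = 5, step_mm = NULL) {
  ps <- sample_perpendicular_profiles(image, line, spacing_along_mm,
                                      half_length_mm, step_mm)
  measure_edge_slopes(ps)$mean_slope
}

#' @export
print.edge_profile_set <- function(x, ...) {
  cat(sprintf("<edge_profile_set> %d profiles (%d dropped at sampling)%s\n",
              length(x$profiles), x$n_dropped,
              if (!is.null(x$mean_slope))
                sprintf(", mean slope %.3f HU/mm over %d usable",
                        x$mean_slope, length(x$slopes)) else ""))
  invisible(x)
}

#' Pearson and Bland-Altman agreement statistics
#'
#' The agreement analysis used for validating automated against reference
#' measurements: Pearson correlation, mean paired difference (`x - y`), the
#' SD of the differences, and the 95% limits of agreement
#' (mean difference +/- 1.96 SD).
#'
#' @param x,y Equal-length numeric vectors (at least 3 pairs).
#' @return A one-row tibble: `pearson_r`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`. `pearson_r` is `NA` (with a warning) when either input
#'   has zero variance.
#' @examples
#' agreement_stats(1:10, 1:10 + 2)
#' @export
agreement_stats <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  r <- if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined", call. = FALSE)
    NA_real_
  } else {
    cor(x, y)
  }
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  tibble::tibble(pearson_r = r, mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(x))
}
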