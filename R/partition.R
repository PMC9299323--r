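#' Erode an organ mask
#'
#' Binary erosion with a structuring element of side/diameter `element_px`
#' (default 7), applied before the SCF map is computed so that windows near
#' the organ boundary do not straddle the edge of the segmentation. The
#' result is always a subset of the input; pixels outside the image are
#' treated as background, so masks touching the image border erode there too.
#'
#' @param mask An [organ_mask()] or matrix.
#' @param element_px Structuring element size in pixels (odd for `"square"`).
#' @param shape `"square"` (exact integral-image erosion) or `"disc"`
#'   (via [EBImage::erode()]).
#' @return The eroded [organ_mask()].
#' @export
erode_mask <- function(mask, element_px = 7L, shape = c("square", "disc")) {
  shape <- match.arg(shape)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  element_px <- as.integer(element_px)
  stopifnot(element_px >= 1L)
  if (element_px == 1L) return(organ_mask(m))
  eroded <- if (shape == "square") {
    if (element_px %% 2L == 0L) stop("square element size must be odd", call. = FALSE)
    box_sum(m * 1, element_px) == element_px^2
  } else {
    matrix(as.numeric(EBImage::erode(m * 1, EBImage::makeBrush(element_px, "disc"))),
           nrow(m), ncol(m)) > 0
  }
  if (!any(eroded)) stop("mask vanished under erosion", call. = FALSE)
  organ_mask(eroded)
}

#' Partition an SCF map into homogeneous and structure-edge regions
#'
#' Computes the `low_pct` and `high_pct` percentiles of the defined SCF values
#' inside the eroded organ mask (linear-interpolation percentile definition,
#' i.e. `stats::quantile()` type 7) and thresholds:
#' the homogeneous region \eqn{R_H} is every pixel with SCF at or below the
#' low cut, the structure-edge region \eqn{R_S} every pixel at or above the
#' high cut. Pixels between the cuts belong to neither region. Ties at a cut
#' are included, so region sizes can exceed the nominal 10% / 30% fractions.
#'
#' Percentiles are computed per slice within the eroded organ mask only,
#' never over the whole image. If the two cut values coincide (a constant SCF
#' map has no measurable structure), all defined pixels are assigned to
#' \eqn{R_H}, \eqn{R_S} is emptied and the partition is flagged `degenerate`.
#'
#' @param scf An [compute_scf_map()] result.
#' @param eroded The eroded [organ_mask()] the map was evaluated on.
#' @param low_pct,high_pct Percentile cut points (defaults 10 and 70).
#' @param min_defined Minimum number of defined SCF pixels required; fewer
#'   raises an error of class `ctiq_too_few_pixels` (the pipeline excludes
#'   the slice with a logged reason).
#' @return An object of class `region_partition` with logical matrices `r_h`
#'   and `r_s` (disjoint subsets of the eroded mask), `eroded_mask`, the cut
#'   values `p10` and `p70` actually used, `n_defined` and `degenerate`.
#' @export
partition_regions <- function(scf, eroded, low_pct = 10, high_pct = 70,
                              min_defined = 100L) {
  stopifnot(inherits(scf, "scf_map"), low_pct < high_pct,
            low_pct >= 0, high_pct <= 100)
  em <- as_mask_matrix(eroded)
  defined <- !is.na(scf$values) & em
  n_defined <- sum(defined)
  if (n_defined < min_defined) {
    stop(structure(
      class = c("ctiq_too_few_pixels", "error", "condition"),
      list(message = sprintf("only %d defined SCF pixels inside eroded mask (need >= %d)",
                             n_defined, min_defined),
           call = NULL)
    ))
  }
  vals <- scf$values[defined]
  cuts <- unname(quantile(vals, c(low_pct, high_pct) / 100, type = 7))
  degenerate <- cuts[1] >= cuts[2]
  if (degenerate) {
    r_h <- defined
    r_s <- matrix(FALSE, nrow(em), ncol(em))
  } else {
    r_h <- defined & scf$values <= cuts[1]
    r_s <- defined & scf$values >= cuts[2]
  }
  structure(
    list(r_h = r_h, r_s = r_s, eroded_mask = organ_mask(em),
         p10 = cuts[1], p70 = cuts[2], n_defined = n_defined,
         low_pct = low_pct, high_pct = high_pct, degenerate = degenerate),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition> %d defined px; R_H %d px (SCF <= %.4g), R_S %d px (SCF >= %.4g)%s\n",
    x$n_defined, sum(x$r_h), x$p10, sum(x$r_s), x$p70,
    if (x$degenerate) " [degenerate: constant SCF]" else ""))
  invisible(x)
}
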