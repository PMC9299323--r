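#' Parameters of the structure coherence feature
#'
#' The SCF of a pixel is the sum of edginess over a square window centered at
#' the pixel, divided by the sum of two directional entropies computed from
#' the same window: the entropy of gradient directions (over \eqn{[-\pi,\pi)})
#' and the entropy of structure-tensor first-eigenvector orientations (over
#' \eqn{[0,\pi)}, since an eigenvector's sign is arbitrary). Edginess is
#' \eqn{I_E = \omega_1 |\nabla I| + \omega_2 |\lambda_1|} where
#' \eqn{\lambda_1} is the first eigenvalue of the structure tensor.
#'
#' Note that \eqn{|\lambda_1|} scales with the square of image contrast while
#' \eqn{|\nabla I|} scales linearly, so with both weights positive the
#' edginess is contrast-inhomogeneous; the default keeps both terms as
#' defined. With `tensor_smooth_sigma_px = 0` the structure tensor is the
#' pointwise outer product of the gradient, which is rank one, so
#' \eqn{\lambda_1 = |\nabla I|^2} identically and the tensor orientation
#' equals the gradient orientation modulo \eqn{\pi}; a positive smoothing
#' sigma averages the tensor over a neighborhood before the eigen-analysis.
#'
#' @param omega1,omega2 Nonnegative edginess weights (their sum must be
#'   positive).
#' @param window_px Odd window side in pixels, at least 3. Default 9
#'   (about 6 mm at typical abdominal CT spacing).
#' @param n_angle_bins Number of equal-width orientation histogram bins,
#'   at least 4.
#' @param entropy_floor Small positive guard added to the entropy sum so
#'   perfectly coherent windows (both entropies zero) do not divide by zero.
#' @param tensor_smooth_sigma_px Gaussian sigma (pixels) for smoothing the
#'   structure tensor components; 0 means pointwise products.
#' @return An object of class `scf_params`.
#' @export
scf_params <- function(omega1 = 1, omega2 = 1, window_px = 9L,
                       n_angle_bins = 8L, entropy_floor = 1e-6,
                       tensor_smooth_sigma_px = 0) {
  window_px <- as.integer(window_px)
  n_angle_bins <- as.integer(n_angle_bins)
  stopifnot(
    omega1 >= 0, omega2 >= 0, omega1 + omega2 > 0,
    window_px >= 3L, window_px %% 2L == 1L,
    n_angle_bins >= 4L,
    entropy_floor > 0,
    tensor_smooth_sigma_px >= 0
  )
  structure(
    list(omega1 = omega1, omega2 = omega2, window_px = window_px,
         n_angle_bins = n_angle_bins, entropy_floor = entropy_floor,
         tensor_smooth_sigma_px = tensor_smooth_sigma_px),
    class = "scf_params"
  )
}

#' Image gradient in physical units
#'
#' Central differences scaled by the per-axis pixel spacing, with edge
#' replication at the border (the border difference therefore spans one pixel
#' but is still divided by `2 * spacing`). `gx` is the derivative along
#' columns, `gy` along rows; the gradient angle is `atan2(gy, gx)`.
#'
#' @param image A [ct_image()].
#' @return An object of class `gradient_field` with matrices `gx`, `gy`,
#'   `magnitude` (HU/mm) and `angle` (radians in \eqn{(-\pi, \pi]}).
#' @export
compute_gradient <- function(image) {
  stopifnot(inherits(image, "ct_image"))
  px <- image$pixels
  nr <- nrow(px)
  nc <- ncol(px)
  # edge replication: pad indices clamp at the border
  up <- px[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- px[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- px[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- px[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  gy <- (dn - up) / (2 * image$spacing[["row"]])
  gx <- (rt - lf) / (2 * image$spacing[["col"]])
  structure(
    list(gx = gx, gy = gy,
         magnitude = sqrt(gx^2 + gy^2),
         angle = atan2(gy, gx),
         spacing = image$spacing),
    class = "gradient_field"
  )
}

#' Structure tensor field and its closed-form eigen-analysis
#'
#' The structure tensor is the (optionally Gaussian-smoothed) matrix of
#' gradient products \eqn{T = [gx^2, gx gy; gx gy, gy^2]}. The first
#' eigenvalue is computed in closed form,
#' \eqn{\lambda_1 = ((T_{11}+T_{22}) + \sqrt{(T_{11}-T_{22})^2 + 4 T_{12}^2})/2},
#' and the first eigenvector as \eqn{(2 T_{12},\; T_{22}-T_{11} +
#' \sqrt{(T_{22}-T_{11})^2 + 4 T_{12}^2})}, which satisfies
#' \eqn{T v = \lambda_1 v}; when \eqn{T_{12} = 0} the formula degenerates and
#' the axis-aligned eigenvector is taken directly. Orientations are folded
#' into \eqn{[0, \pi)}.
#'
#' @param grad A [compute_gradient()] result.
#' @param params An [scf_params()]; only `tensor_smooth_sigma_px` is used.
#' @return An object of class `structure_tensor_field` with matrices `t11`,
#'   `t12`, `t22`, `lambda1` and `vt_angle`.
#' @export
compute_structure_tensor <- function(grad, params = scf_params()) {
  stopifnot(inherits(grad, "gradient_field"))
  t11 <- grad$gx^2
  t12 <- grad$gx * grad$gy
  t22 <- grad$gy^2
  sig <- params$tensor_smooth_sigma_px
  if (sig > 0) {
    t11 <- gaussian_blur(t11, sig)
    t12 <- gaussian_blur(t12, sig)
    t22 <- gaussian_blur(t22, sig)
  }
  disc <- sqrt((t11 - t22)^2 + 4 * t12^2)
  lambda1 <- ((t11 + t22) + disc) / 2
  vx <- 2 * t12
  vy <- (t22 - t11) + disc
  # degenerate diagonal tensors: axis-aligned eigenvector
  deg <- t12 == 0
  vx[deg] <- ifelse(t11[deg] >= t22[deg], 1, 0)
  vy[deg] <- ifelse(t11[deg] >= t22[deg], 0, 1)
  vt_angle <- atan2(vy, vx) %% pi
  structure(
    list(t11 = t11, t12 = t12, t22 = t22, lambda1 = lambda1, vt_angle = vt_angle),
    class = "structure_tensor_field"
  )
}

#' Pixelwise edginess
#'
#' \eqn{I_E = \omega_1 |\nabla I| + \omega_2 |\lambda_1|}: a weighted sum of
#' the gradient magnitude and the first structure-tensor eigenvalue, large
#' where a pixel sits on an anatomical structure.
#'
#' @param grad A [compute_gradient()] result.
#' @param tensor A [compute_structure_tensor()] result on the same grid.
#' @param params An [scf_params()].
#' @return A nonnegative matrix.
#' @export
edginess <- function(grad, tensor, params = scf_params()) {
  stopifnot(inherits(grad, "gradient_field"),
            inherits(tensor, "structure_tensor_field"),
            identical(dim(grad$magnitude), dim(tensor$lambda1)))
  params$omega1 * grad$magnitude + params$omega2 * abs(tensor$lambda1)
}

# Map angles to bin indices 0..n_bins-1 over [-pi, pi) (full circle) or
# [0, pi) (half circle). The wrap point maps onto bin 0.
angle_bins <- function(angles, n_bins, domain) {
  if (domain == "full_circle") {
    b <- floor(((angles + pi) %% (2 * pi)) / (2 * pi) * n_bins)
  } else {
    b <- floor((angles %% pi) / pi * n_bins)
  }
  pmin(pmax(b, 0), n_bins - 1)
}

#' Directional (orientation histogram) entropy
#'
#' Shannon entropy, in nats, of the histogram of angles over `n_bins`
#' equal-width bins spanning \eqn{[-\pi, \pi)} (`"full_circle"`, for gradient
#' directions) or \eqn{[0, \pi)} (`"half_circle"`, for tensor orientations,
#' where a vector and its negation are the same orientation). Angles whose
#' associated gradient magnitude is zero are excluded (their direction is
#' undefined); a window that is empty after exclusion has entropy 0 by
#' convention. The result always lies in \eqn{[0, \ln(n\_bins)]}.
#'
#' @param angles Numeric vector of angles (radians).
#' @param n_bins Number of histogram bins.
#' @param domain `"full_circle"` or `"half_circle"`.
#' @param magnitudes Optional vector of gradient magnitudes used to exclude
#'   zero-magnitude pixels.
#' @return Entropy in nats.
#' @examples
#' directional_entropy(rep(0.3, 10))                        # 0
#' directional_entropy(seq(-pi, pi - 1e-9, length.out = 80))  # ~ log(8)
#' @export
directional_entropy <- function(angles, n_bins = 8L,
                                domain = c("full_circle", "half_circle"),
                                magnitudes = NULL) {
  domain <- match.arg(domain)
  angles <- as.numeric(angles)
  if (!is.null(magnitudes)) angles <- angles[magnitudes > 0]
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) return(0)
  counts <- tabulate(angle_bins(angles, n_bins, domain) + 1L, nbins = n_bins)
  p <- counts[counts > 0] / length(angles)
  -sum(p * log(p))
}

#' Per-pixel structure coherence feature map
#'
#' For every pixel inside the evaluation mask, takes the square window of side
#' `window_px` centered at the pixel, intersected with the mask, and computes
#' \deqn{SCF(p) = \frac{\sum_{(i,j) \in W(p)} I_E(i,j)}{H_G + H_T + \epsilon}}
#' where \eqn{H_G} and \eqn{H_T} are the window's directional entropies of the
#' gradient directions and tensor orientations (zero-magnitude pixels
#' excluded) and \eqn{\epsilon} is the entropy floor. The SCF is large on
#' coherent anatomical edges (large edginess, concentrated orientations) and
#' small in homogeneous or pure-noise regions (small edginess and/or random
#' orientations). The map is computed with exact integral-image window sums,
#' so it matches a per-window brute-force evaluation to machine precision.
#'
#' Pixels outside the mask are undefined (`NA`). Adding a constant to the
#' image leaves the map unchanged (gradients are unaffected).
#'
#' @param image A [ct_image()].
#' @param mask The evaluation mask, normally the eroded organ mask from
#'   [erode_mask()].
#' @param params An [scf_params()].
#' @return An object of class `scf_map` with fields `values` (matrix, `NA`
#'   outside the mask), `window_px`, `params` and `mask`.
#' @export
compute_scf_map <- function(image, mask, params = scf_params()) {
  stopifnot(inherits(image, "ct_image"))
  m <- as_mask_matrix(mask)
  if (!identical(dim(m), dim(image$pixels))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  if (!any(m)) stop("evaluation mask is empty", call. = FALSE)
  win <- params$window_px
  nb <- params$n_angle_bins

  grad <- compute_gradient(image)
  tensor <- compute_structure_tensor(grad, params)
  ie <- edginess(grad, tensor, params)

  valid <- m & (grad$magnitude > 0)
  sum_ie <- box_sum(ie * m, win)
  n_valid <- box_sum(valid * 1, win)

  bins_g <- angle_bins(grad$angle, nb, "full_circle")
  bins_t <- angle_bins(tensor$vt_angle, nb, "half_circle")
  hg <- matrix(0, nrow(m), ncol(m))
  ht <- hg
  for (b in 0:(nb - 1L)) {
    cg <- box_sum((valid & bins_g == b) * 1, win)
    ct <- box_sum((valid & bins_t == b) * 1, win)
    pg <- ifelse(n_valid > 0, cg / n_valid, 0)
    pt <- ifelse(n_valid > 0, ct / n_valid, 0)
    hg <- hg - ifelse(pg > 0, pg * log(pg), 0)
    ht <- ht - ifelse(pt > 0, pt * log(pt), 0)
  }

  values <- sum_ie / (hg + ht + params$entropy_floor)
  values[!m] <- NA_real_
  structure(
    list(values = values, window_px = win, params = params, mask = m,
         entropy_g = ifelse(m, hg, NA_real_), entropy_t = ifelse(m, ht, NA_real_)),
    class = "scf_map"
  )
}

#' @export
print.scf_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<scf_map> %d x %d px, %d defined, window %d px, SCF range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), length(v), x$window_px,
              min(v), max(v)))
  invisible(x)
}
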