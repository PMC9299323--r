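#' Synthetic contrast-enhanced liver slice specification
#'
#' Describes a fully parameterized test image emulating a contrast-enhanced
#' liver CT slice: an elliptical parenchyma region (default 100 HU) on a soft
#' background (-50 HU), containing brighter vessel structures (circular
#' cross-sections and one straight tubular vessel, default +100 HU contrast),
#' with a controllable Gaussian edge blur applied before additive Gaussian
#' noise of tunable magnitude and correlation. The straight tube provides a
#' clean ground-truth edge for the slope oracle.
#'
#' The defaults mirror typical contrast-enhanced liver values (parenchyma
#' near 100 HU, enhanced vessels near 200 HU) on a 256 x 256 grid at 0.7 mm
#' spacing, which gives a parenchyma area well above the 100 cm2 inclusion
#' threshold.
#'
#' @param shape_px Image size `c(rows, cols)`.
#' @param spacing_mm Pixel spacing, `c(row, col)` or one value.
#' @param parenchyma_hu,background_hu,vessel_contrast_hu Intensity levels.
#' @param vessels List of vessel descriptors. Circles:
#'   `list(type = "circle", center = c(row, col), radius_px = r)`. Tubes:
#'   `list(type = "tube", rows = c(r0, r1), cols = c(c0, c1))` (an axis-aligned
#'   bright band). Coordinates are in pixels. `NULL` gives the default layout.
#' @param edge_sigma_px Gaussian blur (pixels) applied to the noiseless render.
#' @param extra_smooth_px Additional Gaussian blur applied after
#'   `edge_sigma_px` (the "intentional smoothing" manipulation; 0 = none).
#' @param unsharp_amount,unsharp_sigma_px Unsharp-mask sharpening applied to
#'   the noiseless render (amount 0 = none).
#' @param noise_sigma_hu Additive Gaussian noise SD in HU.
#' @param noise_correlation_px Gaussian correlation length of the noise
#'   (0 = white); correlated noise is renormalized to `noise_sigma_hu`.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_px = c(256L, 256L), spacing_mm = c(0.7, 0.7),
                         parenchyma_hu = 100, background_hu = -50,
                         vessel_contrast_hu = 100, vessels = NULL,
                         edge_sigma_px = 1.0, extra_smooth_px = 0,
                         unsharp_amount = 0, unsharp_sigma_px = 2,
                         noise_sigma_hu = 10, noise_correlation_px = 0,
                         seed = 1L) {
  shape_px <- as.integer(shape_px)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  stopifnot(length(shape_px) == 2, all(shape_px >= 64L),
            all(spacing_mm > 0), edge_sigma_px >= 0, extra_smooth_px >= 0,
            unsharp_amount >= 0, unsharp_sigma_px > 0,
            noise_sigma_hu >= 0, noise_correlation_px >= 0)
  if (is.null(vessels)) {
    n <- shape_px
    vessels <- list(
      list(type = "circle", center = c(0.40, 0.38) * n, radius_px = 0.035 * min(n)),
      list(type = "circle", center = c(0.62, 0.40) * n, radius_px = 0.022 * min(n)),
      list(type = "circle", center = c(0.36, 0.60) * n, radius_px = 0.05 * min(n)),
      list(type = "tube",
           rows = round(c(0.52, 0.75) * n[1]),
           cols = round(c(0.60, 0.645) * n[2]))
    )
  }
  structure(
    list(shape_px = shape_px,
         spacing_mm = c(row = spacing_mm[1], col = spacing_mm[2]),
         parenchyma_hu = parenchyma_hu, background_hu = background_hu,
         vessel_contrast_hu = vessel_contrast_hu, vessels = vessels,
         edge_sigma_px = edge_sigma_px, extra_smooth_px = extra_smooth_px,
         unsharp_amount = unsharp_amount, unsharp_sigma_px = unsharp_sigma_px,
         noise_sigma_hu = noise_sigma_hu,
         noise_correlation_px = noise_correlation_px,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Unsharp-mask sharpening
#'
#' `I + amount * (I - G_sigma * I)`: adds back a scaled high-pass component.
#'
#' @param pixels Numeric matrix.
#' @param amount Sharpening amount (0 = identity).
#' @param sigma_px Gaussian sigma of the low-pass, in pixels.
#' @return The sharpened matrix.
#' @export
unsharp_mask <- function(pixels, amount, sigma_px = 2) {
  if (amount == 0) return(pixels)
  pixels + amount * (pixels - gaussian_blur(pixels, sigma_px))
}

# ellipse semi-axes used for the parenchyma region, relative to image size
PARENCHYMA_SEMI_AXES <- c(0.45, 0.40)

#' Generate a phantom bundle
#'
#' Rendering order is fixed: draw the noiseless geometry at the stated HU
#' levels, blur with `edge_sigma_px` (then `extra_smooth_px`), apply the
#' unsharp mask if requested, and finally add seeded Gaussian noise. The blur
#' is applied before the noise so that edge blur controls structure sharpness
#' without attenuating the noise; real reconstruction algorithms affect both,
#' which is what [apply_denoiser()] models instead.
#'
#' Ground truth carried in the bundle: the organ mask (the parenchyma
#' ellipse), the set of true edge pixels (noiseless gradient magnitude above
#' 10% of its maximum), a straight edge polyline along the tube vessel's
#' boundary for the slope oracle, the noiseless image, and the true noise SD.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_bundle` with fields `image`,
#'   `noiseless`, `organ_mask`, `truth_edge_pixels`, `truth_edge_line`,
#'   `truth_noise_sigma` and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape_px[1]
  nc <- spec$shape_px[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  ar <- PARENCHYMA_SEMI_AXES[1] * nr
  ac <- PARENCHYMA_SEMI_AXES[2] * nc
  ellipse <- ((rows - cr) / ar)^2 + ((cols - cc) / ac)^2 <= 1

  in_ellipse <- function(r, c) ((r - cr) / ar)^2 + ((c - cc) / ac)^2 <= 1

  px <- matrix(spec$background_hu, nr, nc)
  px[ellipse] <- spec$parenchyma_hu
  vessel_hu <- spec$parenchyma_hu + spec$vessel_contrast_hu
  tube <- NULL
  for (v in spec$vessels) {
    if (v$type == "circle") {
      r0 <- v$center[1]; c0 <- v$center[2]; rad <- v$radius_px
      if (!in_ellipse(r0 - rad, c0) || !in_ellipse(r0 + rad, c0) ||
          !in_ellipse(r0, c0 - rad) || !in_ellipse(r0, c0 + rad)) {
        stop("vessel outside parenchyma ellipse", call. = FALSE)
      }
      px[(rows - r0)^2 + (cols - c0)^2 <= rad^2] <- vessel_hu
    } else if (v$type == "tube") {
      if (!all(in_ellipse(v$rows, v$cols[1])) || !all(in_ellipse(v$rows, v$cols[2]))) {
        stop("vessel outside parenchyma ellipse", call. = FALSE)
      }
      px[v$rows[1]:v$rows[2], v$cols[1]:v$cols[2]] <- vessel_hu
      if (is.null(tube)) tube <- v
    } else {
      stop(sprintf("unknown vessel type '%s'", v$type), call. = FALSE)
    }
  }

  px <- gaussian_blur(px, spec$edge_sigma_px)
  px <- gaussian_blur(px, spec$extra_smooth_px)
  px <- unsharp_mask(px, spec$unsharp_amount, spec$unsharp_sigma_px)
  noiseless <- px

  if (spec$noise_sigma_hu > 0) {
    noise <- with_local_seed(spec$seed, matrix(rnorm(nr * nc), nr, nc))
    if (spec$noise_correlation_px > 0) {
      noise <- gaussian_blur(noise, spec$noise_correlation_px)
      noise <- noise / sd(noise)
    }
    px <- px + spec$noise_sigma_hu * noise
  }

  grad_mag <- compute_gradient(
    ct_image(noiseless, spacing_mm = spec$spacing_mm, id = "noiseless"))$magnitude
  truth_edges <- grad_mag > 0.10 * max(grad_mag)

  truth_line <- NULL
  if (!is.null(tube)) {
    margin <- 3
    truth_line <- edge_line(rbind(
      c(tube$rows[1] + margin, tube$cols[1] - 0.5),
      c(tube$rows[2] - margin, tube$cols[1] - 0.5)
    ))
  }

  structure(
    list(
      image = ct_image(px, spacing_mm = spec$spacing_mm,
                       id = sprintf("phantom-seed%d", spec$seed)),
      noiseless = ct_image(noiseless, spacing_mm = spec$spacing_mm,
                           id = sprintf("phantom-seed%d-noiseless", spec$seed)),
      organ_mask = organ_mask(ellipse),
      truth_edge_pixels = truth_edges,
      truth_edge_line = truth_line,
      truth_noise_sigma = spec$noise_sigma_hu,
      spec = spec
    ),
    class = "phantom_bundle"
  )
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %d x %d px, noise sigma %.1f HU, edge sigma %.2f px, seed %d\n",
              nrow(x$image$pixels), ncol(x$image$pixels), x$truth_noise_sigma,
              x$spec$edge_sigma_px, x$spec$seed))
  invisible(x)
}

#' Generate a sharpness ladder of phantoms
#'
#' One bundle per manipulation: each blur sigma produces a copy additionally
#' smoothed with that sigma, each unsharp amount a sharpened copy. Noise is
#' redrawn per bundle from seeds derived from the base seed, so bundles are
#' independent realizations. With both lists empty the base bundle alone is
#' returned. The noiseless true edge slope is strictly decreasing in blur
#' sigma and increasing in unsharp amount, making the series a valid ladder
#' for calibrating and validating the sharpness index.
#'
#' @param base A [phantom_spec()] (its `extra_smooth_px`/`unsharp_amount`
#'   must be 0).
#' @param blur_sigmas Numeric vector of additional Gaussian sigmas (px).
#' @param unsharp_amounts Numeric vector of unsharp-mask amounts.
#' @return List of `phantom_bundle`s; each spec records its manipulation.
#' @export
generate_sharpness_series <- function(base, blur_sigmas = numeric(0),
                                      unsharp_amounts = numeric(0)) {
  stopifnot(inherits(base, "phantom_spec"),
            base$extra_smooth_px == 0, base$unsharp_amount == 0)
  specs <- list()
  if (length(blur_sigmas) == 0 && length(unsharp_amounts) == 0) {
    specs <- list(base)
  } else {
    for (s in blur_sigmas) {
      sp <- base
      sp$extra_smooth_px <- s
      specs[[length(specs) + 1L]] <- sp
    }
    for (a in unsharp_amounts) {
      sp <- base
      sp$unsharp_amount <- a
      specs[[length(specs) + 1L]] <- sp
    }
  }
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp$seed <- base$seed + 1000L * i  # independent noise per bundle
    generate_phantom(sp)
  })
}

#' Apply a stand-in denoiser to a phantom bundle
#'
#' Models the behaviors a reconstruction algorithm can exhibit, exercising
#' the structure alteration index without clinical reconstructions:
#' * `"ideal"` — convex combination of the noisy and the stored noiseless
#'   image (`strength` of the noise removed uniformly, structure bit-exact).
#'   Its subtraction image is a scaled copy of the very noise field the
#'   reference partition was selected on, so its SAI sits slightly above 1;
#' * `"edge_preserving"` — removes `strength` of the noise only away from
#'   structure (outside the dilated true-edge set) and leaves pixels near
#'   edges untouched, the behavior an ideal edge-preserving denoiser has;
#'   its SAI is below 1;
#' * `"blurring"` — Gaussian smoothing of the noisy image with
#'   `sigma = strength` pixels (noise reduced but edges smeared); SAI above 1;
#' * `"none"` — identity (downstream SAI flags the pair as a no-op).
#'
#' @param bundle A [generate_phantom()] result.
#' @param kind `"ideal"`, `"edge_preserving"`, `"blurring"` or `"none"`.
#' @param strength Denoising strength (fraction in `[0, 1]` for `"ideal"` and
#'   `"edge_preserving"`, sigma in pixels for `"blurring"`).
#' @param edge_halo_px Dilation (square side, px) of the true-edge set that
#'   `"edge_preserving"` leaves untouched.
#' @return A [ct_image()] of the denoised slice.
#' @export
apply_denoiser <- function(bundle,
                           kind = c("ideal", "edge_preserving", "blurring", "none"),
                           strength = 1, edge_halo_px = 9L) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  kind <- match.arg(kind)
  px <- switch(kind,
    ideal = {
      stopifnot(strength >= 0, strength <= 1)
      (1 - strength) * bundle$image$pixels + strength * bundle$noiseless$pixels
    },
    edge_preserving = {
      stopifnot(strength >= 0, strength <= 1)
      noise <- bundle$image$pixels - bundle$noiseless$pixels
      keep <- box_sum(bundle$truth_edge_pixels * 1, as.integer(edge_halo_px)) > 0
      bundle$image$pixels - strength * noise * !keep
    },
    blurring = gaussian_blur(bundle$image$pixels, strength),
    none = bundle$image$pixels
  )
  ct_image(px, spacing_mm = bundle$spec$spacing_mm,
           id = paste0(bundle$image$id, "-", kind))
}

#' Write a phantom bundle as an on-disk fixture
#'
#' Writes the slice as a single-frame DICOM file, the organ mask as PNG, the
#' ground-truth edge line as CSV, and a JSON sidecar with the spec and truth
#' values — the same formats the evaluation pipeline reads, closing the I/O
#' loop for tests.
#'
#' @param bundle A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @param instance_number InstanceNumber for the DICOM file.
#' @return The DICOM path, invisibly.
#' @export
write_phantom_fixture <- function(bundle, dir, stem = "slice001",
                                  instance_number = 1L) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dcm <- file.path(dir, paste0(stem, ".dcm"))
  write_dicom_slice(bundle$image, dcm, instance_number = instance_number,
                    position = c(0, 0, instance_number * 5))
  write_mask_png(bundle$organ_mask, file.path(dir, paste0(stem, "_mask.png")))
  if (!is.null(bundle$truth_edge_line)) {
    write_edge_line(bundle$truth_edge_line, file.path(dir, paste0(stem, "_edge.csv")))
  }
  jsonlite::write_json(
    list(truth_noise_sigma = bundle$truth_noise_sigma,
         edge_sigma_px = bundle$spec$edge_sigma_px,
         extra_smooth_px = bundle$spec$extra_smooth_px,
         unsharp_amount = bundle$spec$unsharp_amount,
         seed = bundle$spec$seed),
    file.path(dir, paste0(stem, "_truth.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dcm)
}
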