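#' Default pipeline configuration
#'
#' Flat nested list of every tunable in the pipeline, in the units the
#' functions take. Serialized to/from YAML by [read_config()], echoed into
#' JSON report mirrors for provenance.
#'
#' @return A named list of configuration sections.
#' @export
default_config <- function() {
  list(
    scf = list(window_px = 9L, omega1 = 1, omega2 = 1, n_angle_bins = 8L,
               entropy_floor = 1e-6, tensor_smooth_sigma_px = 0),
    partition = list(low_pct = 10, high_pct = 70, erosion_px = 7L,
                     erosion_shape = "square"),
    noise = list(roi_size_px = 21L, n_rois = 5L, seed = 1L),
    ssi = list(coef_a = 6.1398, coef_b = 4.2813),
    profile = list(spacing_along_mm = 1, half_length_mm = 5, step_mm = 0.25),
    inclusion = list(min_area_cm2 = 100)
  )
}

#' Read a YAML pipeline configuration
#'
#' Keys missing from the file keep their [default_config()] values.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    if (is.list(user[[section]]) && section %in% names(cfg)) {
      cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

config_scf_params <- function(config) {
  s <- config$scf
  scf_params(omega1 = s$omega1, omega2 = s$omega2, window_px = s$window_px,
             n_angle_bins = s$n_angle_bins, entropy_floor = s$entropy_floor,
             tensor_smooth_sigma_px = s$tensor_smooth_sigma_px)
}

empty_report_row <- function(id) {
  tibble::tibble(
    identifier = id, included = FALSE, reason = NA_character_,
    area_cm2 = NA_real_, noise_hu = NA_real_, roi_size_px = NA_integer_,
    ssi_raw = NA_real_, ssi_calibrated = NA_real_, sai = NA_real_,
    sigma_rs = NA_real_, sigma_rh = NA_real_,
    n_pixels_rh = NA_integer_, n_pixels_rs = NA_integer_,
    p10 = NA_real_, p70 = NA_real_
  )
}

# Shared single-slice pipeline: area filter -> erosion -> SCF -> partition.
# Returns list(row, scf, partition) with row$included FALSE + reason on any
# exclusion.
slice_partition_step <- function(image, mask, config) {
  row <- empty_report_row(image$id)
  if (is.null(mask)) {
    row$reason <- "missing mask"
    return(list(row = row))
  }
  mask <- organ_mask(mask)
  area <- mask_area_cm2(mask, image)
  row$area_cm2 <- area
  if (area <= config$inclusion$min_area_cm2) {
    row$reason <- sprintf("area <= %g cm2", config$inclusion$min_area_cm2)
    return(list(row = row))
  }
  eroded <- tryCatch(
    erode_mask(mask, config$partition$erosion_px, config$partition$erosion_shape),
    error = function(e) e
  )
  if (inherits(eroded, "error")) {
    row$reason <- conditionMessage(eroded)
    return(list(row = row))
  }
  # SCF windows draw on the full organ mask; the erosion guarantees that
  # windows centered on eroded-mask pixels stay (essentially) inside the
  # organ, avoiding a depressed-SCF ring along the mask boundary. The
  # partition then restricts to the eroded mask.
  scf <- compute_scf_map(image, mask, config_scf_params(config))
  part <- tryCatch(
    partition_regions(scf, eroded, config$partition$low_pct, config$partition$high_pct),
    error = function(e) e
  )
  if (inherits(part, "error")) {
    row$reason <- conditionMessage(part)
    return(list(row = row))
  }
  if (part$degenerate) {
    row$reason <- "unpartitionable"
    return(list(row = row))
  }
  row$included <- TRUE
  row$n_pixels_rh <- sum(part$r_h)
  row$n_pixels_rs <- sum(part$r_s)
  row$p10 <- part$p10
  row$p70 <- part$p70
  list(row = row, scf = scf, partition = part)
}

slice_metrics_step <- function(row, image, scf, partition, config, seed) {
  nl <- tryCatch(
    noise_level(image, partition, config$noise$roi_size_px, config$noise$n_rois,
                seed = seed),
    error = function(e) e
  )
  if (inherits(nl, "error")) {
    row$included <- FALSE
    row$reason <- conditionMessage(nl)
    return(row)
  }
  row$noise_hu <- nl$noise_hu
  row$roi_size_px <- nl$roi_size_px
  ssi <- structure_sharpness(scf, partition, config$ssi$coef_a, config$ssi$coef_b)
  row$ssi_raw <- ssi$ssi_raw
  row$ssi_calibrated <- ssi$ssi_calibrated
  row
}

#' Evaluate image quality on one or more slices
#'
#' Runs the full automated pipeline per slice: the `> 100 cm2` organ-area
#' filter, mask erosion, SCF map, percentile partition, noise level and SSI.
#' Every input slice yields exactly one report row; excluded slices carry a
#' reason instead of metric values.
#'
#' @param slices A [ct_image()] or list of them.
#' @param masks An [organ_mask()] (or matrix), a list of them matching
#'   `slices`, or `NULL` entries for slices without masks.
#' @param config Configuration list from [default_config()]/[read_config()].
#' @param seed Base RNG seed; slice `i` uses `seed + i - 1` for its noise
#'   ROIs, so reports are byte-reproducible.
#' @return A tibble with one row per slice: identifier, inclusion flag and
#'   reason, area, noise level (HU), raw and calibrated SSI, region pixel
#'   counts and the SCF cut values.
#' @export
evaluate_quality <- function(slices, masks, config = default_config(), seed = 1L) {
  if (inherits(slices, "ct_image")) slices <- list(slices)
  if (inherits(masks, "organ_mask") || is.matrix(masks)) masks <- list(masks)
  stopifnot(length(slices) == length(masks))
  rows <- lapply(seq_along(slices), function(i) {
    step <- slice_partition_step(slices[[i]], masks[[i]], config)
    if (!step$row$included) return(step$row)
    slice_metrics_step(step$row, slices[[i]], step$scf, step$partition,
                       config, seed + i - 1L)
  })
  dplyr::bind_rows(rows)
}

#' Compare two co-registered reconstructions
#'
#' Everything [evaluate_quality()] does on the reference slices, plus the
#' structure alteration index per slice. The partition is computed on the
#' reference image and reused on the subtraction image, so the same regions
#' are interrogated in both domains.
#'
#' @param reference,target Lists of congruent [ct_image()]s (e.g. FBP and an
#'   iteratively reconstructed or learned-denoiser series), slice-matched.
#' @inheritParams evaluate_quality
#' @return The [evaluate_quality()] tibble with `sai`, `sigma_rs` and
#'   `sigma_rh` columns filled in.
#' @export
compare_reconstructions <- function(reference, target, masks,
                                    config = default_config(), seed = 1L) {
  if (inherits(reference, "ct_image")) reference <- list(reference)
  if (inherits(target, "ct_image")) target <- list(target)
  if (inherits(masks, "organ_mask") || is.matrix(masks)) masks <- list(masks)
  if (length(reference) != length(target)) {
    stop("reference and target series have different slice counts", call. = FALSE)
  }
  stopifnot(length(reference) == length(masks))
  rows <- lapply(seq_along(reference), function(i) {
    step <- slice_partition_step(reference[[i]], masks[[i]], config)
    if (!step$row$included) return(step$row)
    row <- slice_metrics_step(step$row, reference[[i]], step$scf, step$partition,
                              config, seed + i - 1L)
    if (!row$included) return(row)
    sai <- structure_alteration(reference[[i]], target[[i]], step$partition)
    row$sai <- sai$sai
    row$sigma_rs <- sai$sigma_rs
    row$sigma_rh <- sai$sigma_rh
    if (!is.na(sai$flag)) row$reason <- sai$flag
    row
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a directory of DICOM slices against PNG masks
#'
#' For each DICOM slice `<stem>.dcm` the mask `<stem>_mask.png` is looked up
#' in `masks_dir`; slices without a mask are reported as excluded.
#'
#' @param images_dir Directory of single-slice DICOM files.
#' @param masks_dir Directory of `<stem>_mask.png` masks (defaults to
#'   `images_dir`).
#' @param config Configuration list.
#' @param out Optional CSV path passed to [write_quality_report()].
#' @param seed Base RNG seed.
#' @return The report tibble.
#' @export
evaluate_directory <- function(images_dir, masks_dir = images_dir,
                               config = default_config(), out = NULL, seed = 1L) {
  series <- load_dicom_series(images_dir)
  slices <- lapply(series, `[[`, "image")
  masks <- lapply(series, function(s) {
    stem <- tools::file_path_sans_ext(basename(s$meta$path))
    p <- file.path(masks_dir, paste0(stem, "_mask.png"))
    if (file.exists(p)) read_mask_png(p) else NULL
  })
  report <- evaluate_quality(slices, masks, config, seed)
  if (!is.null(out)) write_quality_report(report, out, config)
  report
}

#' Compare two directories of co-registered reconstructions
#'
#' @param reference_dir,target_dir Directories of slice-matched DICOM files.
#' @inheritParams evaluate_directory
#' @return The report tibble with SAI columns.
#' @export
compare_directories <- function(reference_dir, target_dir,
                                masks_dir = reference_dir,
                                config = default_config(), out = NULL, seed = 1L) {
  ref <- load_dicom_series(reference_dir)
  tgt <- load_dicom_series(target_dir)
  if (length(ref) != length(tgt)) {
    stop("reference and target series have different slice counts", call. = FALSE)
  }
  masks <- lapply(ref, function(s) {
    stem <- tools::file_path_sans_ext(basename(s$meta$path))
    p <- file.path(masks_dir, paste0(stem, "_mask.png"))
    if (file.exists(p)) read_mask_png(p) else NULL
  })
  report <- compare_reconstructions(lapply(ref, `[[`, "image"),
                                    lapply(tgt, `[[`, "image"),
                                    masks, config, seed)
  if (!is.null(out)) write_quality_report(report, out, config)
  report
}

#' Synthetic validation of the automated metrics
#'
#' Reruns, on synthetic phantoms, the two agreement analyses used to validate
#' the automated measurements:
#'
#' 1. **Noise recovery** — phantoms at each noise SD in `noise_sigmas`
#'    (`n_per_sigma` independent seeds each) are pushed through the full
#'    pipeline and the automated noise level is compared with the generator
#'    truth (Pearson correlation and Bland-Altman statistics).
#' 2. **Sharpness agreement** — a sharpness ladder (`blur_sigmas` smoothing
#'    and `unsharp_amounts` sharpening manipulations, replicated over
#'    `n_series_seeds` base phantoms) is measured both by the raw SSI and by
#'    the perpendicular-profile slope oracle along the ground-truth edge
#'    line; the two are correlated and a linear SSI calibration is fitted.
#'
#' @param seed Base seed for all phantom generation.
#' @param noise_sigmas True noise SDs (HU) for the recovery study.
#' @param n_per_sigma Phantoms per noise level.
#' @param blur_sigmas,unsharp_amounts Sharpness-ladder manipulations.
#' @param n_series_seeds Independent base phantoms for the ladder.
#' @param config Pipeline configuration.
#' @return An object of class `ctiq_validation`: tibbles `noise` and
#'   `sharpness`, the `noise_agreement` row, the fitted `calibration` and
#'   `sharpness_r`.
#' @export
run_validation <- function(seed = 1L,
                           noise_sigmas = c(5, 10, 20, 40), n_per_sigma = 10L,
                           blur_sigmas = seq(0.2, 1.6, by = 0.2),
                           unsharp_amounts = c(1.5, 2.0, 2.5),
                           n_series_seeds = 4L,
                           config = default_config()) {
  noise_rows <- list()
  for (sig in noise_sigmas) {
    for (k in seq_len(n_per_sigma)) {
      ph_seed <- seed + 7919L * match(sig, noise_sigmas) + k
      bundle <- generate_phantom(phantom_spec(noise_sigma_hu = sig, seed = ph_seed))
      rep <- evaluate_quality(bundle$image, bundle$organ_mask, config, seed = ph_seed)
      noise_rows[[length(noise_rows) + 1L]] <- tibble::tibble(
        true_sigma = sig, seed = ph_seed, noise_hu = rep$noise_hu,
        rel_error = (rep$noise_hu - sig) / sig
      )
    }
  }
  noise_tbl <- dplyr::bind_rows(noise_rows)
  noise_agreement <- agreement_stats(noise_tbl$noise_hu, noise_tbl$true_sigma)

  sharp_rows <- list()
  for (k in seq_len(n_series_seeds)) {
    base <- phantom_spec(seed = seed + 104729L * k)
    bundles <- c(generate_sharpness_series(base),
                 generate_sharpness_series(base, blur_sigmas = blur_sigmas),
                 generate_sharpness_series(base, unsharp_amounts = unsharp_amounts))
    for (b in bundles) {
      rep <- evaluate_quality(b$image, b$organ_mask, config, seed = b$spec$seed)
      xi <- edge_slope_reference(b$image, b$truth_edge_line,
                                 config$profile$spacing_along_mm,
                                 config$profile$half_length_mm,
                                 config$profile$step_mm)
      sharp_rows[[length(sharp_rows) + 1L]] <- tibble::tibble(
        base_seed = base$seed,
        extra_smooth_px = b$spec$extra_smooth_px,
        unsharp_amount = b$spec$unsharp_amount,
        ssi_raw = rep$ssi_raw, oracle_slope = xi
      )
    }
  }
  sharp_tbl <- dplyr::bind_rows(sharp_rows)
  calibration <- fit_ssi_calibration(
    tibble::tibble(ssi_raw = sharp_tbl$ssi_raw, slope = sharp_tbl$oracle_slope))

  structure(
    list(noise = noise_tbl, noise_agreement = noise_agreement,
         sharpness = sharp_tbl, calibration = calibration,
         sharpness_r = calibration$pearson_r, seed = seed),
    class = "ctiq_validation"
  )
}

#' @export
print.ctiq_validation <- function(x, ...) {
  cat("<ctiq_validation>\n")
  cat(sprintf("  noise recovery: %d phantoms, r = %.4f, mean diff = %.3f HU\n",
              nrow(x$noise), x$noise_agreement$pearson_r, x$noise_agreement$mean_diff))
  grand <- dplyr::summarise(dplyr::group_by(x$noise, .data$true_sigma),
                            mean_rel_error = mean(.data$rel_error))
  for (i in seq_len(nrow(grand))) {
    cat(sprintf("    sigma %4.0f HU: mean relative error %+.1f%%\n",
                grand$true_sigma[i], 100 * grand$mean_rel_error[i]))
  }
  cat(sprintf("  sharpness agreement: %d images, SSI vs oracle slope r = %.4f\n",
              nrow(x$sharpness), x$sharpness_r))
  cat(sprintf("  fitted calibration: slope = %.4f * ssi_raw + %.4f\n",
              x$calibration$coef_a, x$calibration$coef_b))
  invisible(x)
}

#' Write a validation result as JSON
#'
#' @param validation A [run_validation()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(validation, path) {
  stopifnot(inherits(validation, "ctiq_validation"))
  jsonlite::write_json(
    list(
      noise = validation$noise,
      noise_agreement = validation$noise_agreement,
      sharpness = validation$sharpness,
      sharpness_r = validation$sharpness_r,
      calibration = list(coef_a = validation$calibration$coef_a,
                         coef_b = validation$calibration$coef_b,
                         pearson_r = validation$calibration$pearson_r,
                         n = validation$calibration$n),
      seed = validation$seed
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a directory of phantom fixtures
#'
#' Generates `n_slices` phantom bundles (consecutive seeds) and writes each as
#' DICOM + mask PNG + edge-line CSV + truth JSON via [write_phantom_fixture()].
#'
#' @param dir Output directory.
#' @param spec Base [phantom_spec()]; slice `i` uses `spec$seed + i - 1`.
#' @param n_slices Number of slices.
#' @return The directory, invisibly.
#' @export
make_fixture_set <- function(dir, spec = phantom_spec(), n_slices = 3L) {
  for (i in seq_len(n_slices)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    write_phantom_fixture(generate_phantom(sp), dir,
                          stem = sprintf("slice%03d", i), instance_number = i)
  }
  invisible(dir)
}
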