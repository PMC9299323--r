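test_that("noise level of a constant image is zero", {
  img <- ct_image(matrix(100, 64, 64), spacing_mm = 1)
  rh <- matrix(FALSE, 64, 64)
  rh[10:50, 10:50] <- TRUE
  part <- manual_partition(rh, matrix(FALSE, 64, 64))
  nl <- noise_level(img, part, roi_size_px = 9, seed = 1)
  expect_equal(nl$noise_hu, 0)
})

test_that("noise level is exactly reproducible and seed-stable", {
  b <- generate_phantom(small_phantom_spec(seed = 21))
  bp <- bundle_partition(b)
  n1 <- suppressMessages(noise_level(b$image, bp$partition, seed = 5))
  n2 <- suppressMessages(noise_level(b$image, bp$partition, seed = 5))
  expect_identical(n1$noise_hu, n2$noise_hu)
  expect_identical(n1$roi_centers, n2$roi_centers)

  n3 <- suppressMessages(noise_level(b$image, bp$partition, seed = 6))
  expect_false(identical(n1$roi_centers, n3$roi_centers))
  # different seeds sample different ROIs but agree on the noise scale
  expect_lt(abs(n1$noise_hu - n3$noise_hu) / n1$noise_hu, 0.10)
})

test_that("ROIs are fully contained in R_H and shrink when it is tight", {
  img <- ct_image(matrix(rnorm(64 * 64), 64, 64), spacing_mm = 1)
  rh <- matrix(FALSE, 64, 64)
  rh[20:32, 20:32] <- TRUE  # hosts 13^2 -> at most size 13; request 21
  part <- manual_partition(rh, matrix(FALSE, 64, 64))
  nl <- suppressMessages(noise_level(img, part, roi_size_px = 21, seed = 1))
  expect_lte(nl$roi_size_px, 13)
  h <- nl$roi_size_px %/% 2
  for (i in seq_len(nrow(nl$roi_centers))) {
    rows <- (nl$roi_centers[i, 1] - h):(nl$roi_centers[i, 1] + h)
    cols <- (nl$roi_centers[i, 2] - h):(nl$roi_centers[i, 2] + h)
    expect_true(all(rh[rows, cols]))
  }

  # a region that cannot host even 5 px ROIs errors out
  tiny <- matrix(FALSE, 64, 64)
  tiny[30:33, 30:33] <- TRUE
  expect_error(noise_level(img, manual_partition(tiny, tiny), seed = 1),
               "R_H too fragmented")
})

test_that("noise scales linearly and SAI is scale-invariant", {
  b <- generate_phantom(small_phantom_spec(seed = 4))
  bp <- bundle_partition(b)
  target <- apply_denoiser(b, "blurring", 1.2)
  a <- 3.7

  n1 <- suppressMessages(noise_level(b$image, bp$partition, seed = 2))
  img_scaled <- ct_image(a * b$image$pixels, spacing_mm = 1)
  n2 <- suppressMessages(noise_level(img_scaled, bp$partition, seed = 2))
  expect_equal(n2$noise_hu, a * n1$noise_hu, tolerance = 1e-12)

  s1 <- structure_alteration(b$image, target, bp$partition)
  s2 <- structure_alteration(img_scaled,
                             ct_image(a * target$pixels, spacing_mm = 1),
                             bp$partition)
  expect_equal(s2$sai, s1$sai, tolerance = 1e-12)
})

test_that("SSI is the mean SCF over R_S and maps through the calibration", {
  mask <- matrix(TRUE, 20, 20)
  rs <- matrix(FALSE, 20, 20)
  rs[5:8, 5:8] <- TRUE
  vals <- matrix(1, 20, 20)
  vals[rs] <- 3.5
  part <- manual_partition(matrix(FALSE, 20, 20), rs)
  res <- structure_sharpness(manual_scf_map(vals, mask), part)
  expect_equal(res$ssi_raw, 3.5)
  expect_equal(res$ssi_calibrated, 6.1398 * 3.5 + 4.2813)

  # zero sharpness lands on the calibration intercept
  res0 <- structure_sharpness(manual_scf_map(matrix(0, 20, 20), mask), part)
  expect_equal(res0$ssi_calibrated, 4.2813)

  # empty structure region is flagged, not an error
  empty <- structure_sharpness(manual_scf_map(vals, mask),
                               manual_partition(rs, matrix(FALSE, 20, 20)))
  expect_equal(empty$flag, "empty R_S")
  expect_true(is.na(empty$ssi_raw))
})

test_that("SSI calibration recovers exact lines and flags bad input", {
  x <- c(1, 2, 3, 4, 7)
  fit <- fit_ssi_calibration(data.frame(ssi_raw = x, slope = 2 * x + 1))
  expect_equal(fit$coef_a, 2)
  expect_equal(fit$coef_b, 1)
  expect_equal(fit$pearson_r, 1)

  fit2 <- fit_ssi_calibration(data.frame(ssi_raw = x, slope = 6.1398 * x + 4.2813))
  expect_equal(fit2$coef_a, 6.1398)
  expect_equal(fit2$coef_b, 4.2813)

  fit3 <- fit_ssi_calibration(data.frame(ssi_raw = x, slope = -x + 10))
  expect_equal(fit3$pearson_r, -1)

  expect_error(fit_ssi_calibration(data.frame(ssi_raw = 1:2, slope = 1:2)), "at least 3")
  expect_error(fit_ssi_calibration(data.frame(ssi_raw = rep(1, 5), slope = 1:5)),
               "constant predictor")

  expect_equal(tidy(fit)$estimate, c(1, 2))
  expect_equal(glance(fit)$pearson_r, 1)
})

test_that("identical reconstructions are flagged as a no-op pair", {
  b <- generate_phantom(small_phantom_spec(seed = 6))
  bp <- bundle_partition(b)
  res <- structure_alteration(b$image, apply_denoiser(b, "none"), bp$partition)
  expect_equal(res$flag, "no-op denoiser")
  expect_true(is.na(res$sai))

  other <- ct_image(matrix(0, 32, 32), spacing_mm = 1)
  expect_error(structure_alteration(b$image, other, bp$partition), "shapes differ")
})

test_that("SAI separates edge-preserving from blurring denoisers", {
  b <- generate_phantom(small_phantom_spec(seed = 8))
  bp <- bundle_partition(b)
  sai_ep <- structure_alteration(b$image, apply_denoiser(b, "edge_preserving", 0.5),
                                 bp$partition)$sai
  sai_bl <- structure_alteration(b$image, apply_denoiser(b, "blurring", 1.5),
                                 bp$partition)$sai
  expect_lt(sai_ep, 1)
  expect_gt(sai_bl, 1)
  expect_gt(sai_bl, sai_ep)
})
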