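test_that("edge lines validate their vertices", {
  expect_error(edge_line(matrix(1, 1, 2)), ">= 2 vertices")
  expect_error(edge_line(rbind(c(1, 1), c(1, 1))), "distinct")
  l <- edge_line(rbind(c(10, 20.5), c(40, 20.5)))
  expect_s3_class(l, "edge_line")
})

test_that("profiles along a straight edge are identical and rising", {
  n <- 64
  step <- matrix(0, n, n)
  step[, 33:n] <- 100  # left dark, right bright
  img <- ct_image(step, spacing_mm = 1)
  line <- edge_line(rbind(c(15, 32.5), c(50, 32.5)))
  ps <- sample_perpendicular_profiles(img, line, spacing_along_mm = 5,
                                      half_length_mm = 6, step_mm = 1)
  expect_gt(length(ps$profiles), 2)
  first <- ps$profiles[[1]]
  for (p in ps$profiles) expect_equal(p$hu, first$hu)
  expect_gt(mean(first$hu[first$s_mm > max(first$s_mm) / 2]),
            mean(first$hu[first$s_mm < max(first$s_mm) / 2]))

  # origin spacing equal to the full length yields exactly the two endpoints
  ps2 <- sample_perpendicular_profiles(img, line, spacing_along_mm = 35,
                                       half_length_mm = 6, step_mm = 1)
  expect_length(ps2$profiles, 2)
})

test_that("profiles that exit the image are dropped with a warning", {
  n <- 64
  ramp <- matrix(rep(1:n, each = n), n, n)  # rising along columns
  img <- ct_image(ramp, spacing_mm = 1)
  # diagonal line marching toward the bottom border: its later perpendiculars
  # exit the image while the earlier ones fit
  line <- edge_line(rbind(c(35, 12), c(60, 37)))
  expect_warning(
    ps <- sample_perpendicular_profiles(img, line, spacing_along_mm = 3,
                                        half_length_mm = 9, step_mm = 1),
    "dropped"
  )
  expect_gt(ps$n_dropped, 0)
  expect_gt(length(ps$profiles), 0)
})

test_that("10-90% clipping follows the quartile-baseline rule", {
  # dense linear ramp: baseline is the mean of the first quartile of samples,
  # thresholds at baseline + 10% / 90% of (max - baseline)
  s <- seq(0, 10, by = 0.05)
  prof <- tibble::tibble(s_mm = s, hu = 10 * s)
  clipped <- clip_profile_10_90(prof)
  baseline <- mean(prof$hu[seq_len(floor(length(s) / 4))])
  lo <- baseline + 0.10 * (100 - baseline)
  hi <- baseline + 0.90 * (100 - baseline)
  expect_equal(min(clipped$hu), prof$hu[which(prof$hu >= lo)[1]])
  expect_equal(max(clipped$hu), prof$hu[which(prof$hu >= hi)[1]])

  # flat profiles are unusable
  expect_null(clip_profile_10_90(tibble::tibble(s_mm = s, hu = rep(5, length(s)))))
  # too-short rises are unusable
  expect_null(clip_profile_10_90(tibble::tibble(s_mm = 0:7, hu = c(0, 0, 0, 0, 0, 0, 0, 100))))
})

test_that("clipping an erf edge lands on the analytic 10-90% positions", {
  sigma <- 1
  s <- seq(-5, 5, by = 0.05)
  prof <- tibble::tibble(s_mm = s, hu = 100 * pnorm(s / sigma))
  clipped <- clip_profile_10_90(prof)
  # baseline ~ 0 (first quartile is deep in the flat tail), so the clip points
  # are the 10% and 90% quantile positions of the Gaussian edge spread
  expect_lt(abs(min(clipped$s_mm) - (-5) - (5 + sigma * qnorm(0.10))), 0.05 + 0.06)
  expect_lt(abs(max(clipped$s_mm) - (-5) - (5 + sigma * qnorm(0.90))), 0.05 + 0.06)
})

test_that("profile slope is the OLS cov/var ratio with its invariances", {
  s <- seq(0, 4, by = 0.5)
  expect_equal(profile_slope(tibble::tibble(s_mm = s, hu = 5 * s + 3)), 5)
  expect_equal(profile_slope(tibble::tibble(s_mm = s, hu = -2 * s)), -2)
  expect_error(profile_slope(tibble::tibble(s_mm = rep(1, 5), hu = 1:5)), "constant")

  set.seed(3)
  hu <- rnorm(length(s))
  base <- profile_slope(tibble::tibble(s_mm = s, hu = hu))
  expect_equal(profile_slope(tibble::tibble(s_mm = s + 12.3, hu = hu)), base)
  expect_equal(profile_slope(tibble::tibble(s_mm = s, hu = 4 * hu)), 4 * base)
})

test_that("mean slope decreases strictly with Gaussian edge blur", {
  slopes <- vapply(c(0.5, 1.0, 1.6, 2.4), function(sig) {
    img <- erf_edge_image(n = 128, spacing = 0.5, sigma_mm = sig)
    line <- edge_line(rbind(c(30, 64.5), c(98, 64.5)))
    edge_slope_reference(img, line, spacing_along_mm = 4, half_length_mm = 8,
                         step_mm = 0.1)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("agreement statistics match their definitions", {
  x <- c(1, 5, 9, 13.5)
  ident <- agreement_stats(x, x)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$mean_diff, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  shifted <- agreement_stats(x, x + 2)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$mean_diff, -2)

  y <- c(2, 5, 8)
  d <- agreement_stats(y + c(-1, 0, 1), y)
  expect_equal(d$mean_diff, 0)
  expect_equal(d$sd_diff, 1)
  expect_equal(c(d$loa_low, d$loa_high), c(-1.96, 1.96))

  expect_warning(r0 <- agreement_stats(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0$pearson_r))
})
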