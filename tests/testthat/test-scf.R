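test_that("gradients are central differences in HU/mm", {
  n <- 24
  ramp <- matrix(rep(5 * (1:n), each = n), n, n)  # I = 5 * col at 1 mm spacing
  g <- compute_gradient(ct_image(ramp, spacing_mm = 1))
  interior <- 2:(n - 1)
  expect_equal(g$gx[interior, interior], matrix(5, n - 2, n - 2))
  expect_equal(g$gy, matrix(0, n, n))
  expect_equal(g$magnitude[interior, interior], matrix(5, n - 2, n - 2))

  # constant image: zero everywhere
  g0 <- compute_gradient(ct_image(matrix(7, n, n), spacing_mm = 1))
  expect_true(all(g0$magnitude == 0))

  # units contract: 5 HU per pixel at 0.5 mm spacing is 10 HU/mm
  g2 <- compute_gradient(ct_image(ramp, spacing_mm = 0.5))
  expect_equal(g2$magnitude[interior, interior], matrix(10, n - 2, n - 2))

  # magnitude^2 = gx^2 + gy^2
  set.seed(1)
  gr <- compute_gradient(ct_image(matrix(rnorm(n * n), n, n), spacing_mm = 0.7))
  expect_equal(gr$magnitude^2, gr$gx^2 + gr$gy^2, tolerance = 1e-12)
})

test_that("structure tensor closed forms match hand values", {
  n <- 20
  # pure-x gradient gx = 3: ramp 3 HU/px at 1 mm
  g <- compute_gradient(ct_image(matrix(rep(3 * (1:n), each = n), n, n), spacing_mm = 1))
  t <- compute_structure_tensor(g)
  i <- 10; j <- 10
  expect_equal(t$t11[i, j], 9)
  expect_equal(t$t12[i, j], 0)
  expect_equal(t$t22[i, j], 0)
  expect_equal(t$lambda1[i, j], 9)
  expect_equal(t$vt_angle[i, j], 0)

  # gx = gy = 1: diagonal ramp
  d <- matrix(0, n, n)
  for (r in 1:n) d[r, ] <- r + (1:n)
  g2 <- compute_gradient(ct_image(d, spacing_mm = 1))
  t2 <- compute_structure_tensor(g2)
  expect_equal(t2$t11[i, j], 1)
  expect_equal(t2$t12[i, j], 1)
  expect_equal(t2$t22[i, j], 1)
  expect_equal(t2$lambda1[i, j], 2)
  expect_equal(t2$vt_angle[i, j], pi / 4)
})

test_that("eigen-relation T v = lambda1 v holds pointwise on random smoothed tensors", {
  set.seed(7)
  img <- ct_image(matrix(rnorm(40 * 40, 0, 50), 40, 40), spacing_mm = 0.7)
  g <- compute_gradient(img)
  t <- compute_structure_tensor(g, scf_params(tensor_smooth_sigma_px = 1.5))
  vx <- cos(t$vt_angle)
  vy <- sin(t$vt_angle)
  resid_x <- t$t11 * vx + t$t12 * vy - t$lambda1 * vx
  resid_y <- t$t12 * vx + t$t22 * vy - t$lambda1 * vy
  expect_lt(max(abs(resid_x)), 1e-10)
  expect_lt(max(abs(resid_y)), 1e-10)
  # lambda1 is the larger root: at least the mean of the trace
  expect_true(all(t$lambda1 >= (t$t11 + t$t22) / 2 - 1e-12))
})

test_that("edginess is the weighted sum of |grad| and |lambda1|", {
  n <- 20
  g <- compute_gradient(ct_image(matrix(rep(3 * (1:n), each = n), n, n), spacing_mm = 1))
  t <- compute_structure_tensor(g)
  i <- 10; j <- 10
  expect_equal(edginess(g, t, scf_params(omega1 = 1, omega2 = 0))[i, j], 3)
  expect_equal(edginess(g, t, scf_params(omega1 = 0, omega2 = 1))[i, j], 9)
  expect_equal(edginess(g, t, scf_params(omega1 = 0.5, omega2 = 0.5))[i, j], 6)
  expect_true(all(edginess(g, t, scf_params()) >= 0))
})

test_that("directional entropy handles the canonical histograms", {
  expect_equal(directional_entropy(rep(0.3, 25)), 0)
  # uniform occupancy of all 8 bins
  centers <- -pi + (2 * pi) * (0:7 + 0.5) / 8
  expect_equal(directional_entropy(rep(centers, 10), n_bins = 8), log(8))
  # 16 samples split equally over two bins
  expect_equal(directional_entropy(c(rep(centers[2], 8), rep(centers[5], 8))), log(2))
  # zero-magnitude pixels are excluded; empty-after-exclusion windows give 0
  expect_equal(directional_entropy(c(0.1, 2.0), magnitudes = c(1, 0)), 0)
  expect_equal(directional_entropy(numeric(0)), 0)
  # half-circle domain folds orientations: theta and theta + pi coincide
  expect_equal(directional_entropy(c(0.4, 0.4 + pi), domain = "half_circle"), 0)
})

test_that("entropy bounds hold for random angle sets and bin counts", {
  set.seed(11)
  for (nb in c(4L, 8L, 16L)) {
    for (k in 1:20) {
      a <- runif(sample(1:200, 1), -pi, pi)
      h <- directional_entropy(a, n_bins = nb)
      expect_gte(h, 0)
      expect_lte(h, log(nb) + 1e-12)
    }
  }
})

test_that("the SCF map equals a per-window brute-force evaluation", {
  set.seed(23)
  n <- 24
  img <- ct_image(matrix(round(rnorm(n * n, 80, 30)), n, n), spacing_mm = c(0.7, 0.9))
  mask <- matrix(FALSE, n, n)
  mask[4:21, 3:22] <- TRUE
  mask[10:12, 10:15] <- FALSE  # a hole, to exercise window-mask intersection

  for (win in c(5L, 9L)) {
    params <- scf_params(window_px = win)
    map <- compute_scf_map(img, mask, params)

    grad <- compute_gradient(img)
    tensor <- compute_structure_tensor(grad, params)
    ie <- edginess(grad, tensor, params)
    h <- win %/% 2L
    for (p in sample(which(mask), 40)) {
      r <- (p - 1) %% n + 1
      c <- (p - 1) %/% n + 1
      rr <- max(1, r - h):min(n, r + h)
      cc <- max(1, c - h):min(n, c + h)
      inside <- mask[rr, cc]
      valid <- inside & grad$magnitude[rr, cc] > 0
      hg <- directional_entropy(grad$angle[rr, cc][valid], params$n_angle_bins, "full_circle")
      ht <- directional_entropy(tensor$vt_angle[rr, cc][valid], params$n_angle_bins, "half_circle")
      expected <- sum(ie[rr, cc][inside]) / (hg + ht + params$entropy_floor)
      expect_equal(map$values[r, c], expected, tolerance = 1e-12)
    }
    expect_true(all(is.na(map$values[!mask])))
    expect_true(all(map$values[mask] >= 0))
  }
})

test_that("a constant image has SCF identically zero", {
  img <- ct_image(matrix(42, 32, 32), spacing_mm = 1)
  mask <- matrix(TRUE, 32, 32)
  map <- compute_scf_map(img, mask)
  expect_true(all(map$values == 0))
})

test_that("a coherent edge window outscores an equal-contrast noise window", {
  n <- 21
  step <- matrix(0, n, n)
  step[, 11:n] <- 100  # straight vertical edge, contrast 100
  set.seed(5)
  noise <- matrix(rnorm(n * n, 0, 100), n, n)
  mask <- matrix(TRUE, n, n)
  scf_edge <- compute_scf_map(ct_image(step, spacing_mm = 1), mask)$values[11, 11]
  scf_noise <- compute_scf_map(ct_image(noise, spacing_mm = 1), mask)$values[11, 11]
  expect_gt(scf_edge, scf_noise)
})

test_that("on phantoms, true edges carry higher mean SCF than parenchyma interior", {
  for (sigma in c(5, 40)) {
    b <- generate_phantom(small_phantom_spec(noise_sigma_hu = sigma, seed = 17))
    eroded <- erode_mask(b$organ_mask)
    map <- compute_scf_map(b$image, b$organ_mask)
    edge <- b$truth_edge_pixels & eroded$mask
    interior <- eroded$mask & !edge
    expect_gt(mean(map$values[edge]), mean(map$values[interior]))
  }
})
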