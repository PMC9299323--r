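test_that("DICOM rescale is affine and the round trip is exact on stored values", {
  # stored 1124 with slope 1, intercept -1024 must read back as 100 HU
  hu <- matrix(-50, 32, 32)
  hu[16, 16] <- 100
  img <- ct_image(hu, spacing_mm = c(0.7, 0.8), id = "t1")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, path, rescale_slope = 1, rescale_intercept = -1024)

  rt <- read_dicom_slice(path)
  expect_equal(rt$image$pixels, hu)  # integer HU survive exactly
  expect_equal(unname(rt$image$spacing), c(0.7, 0.8))
  expect_equal(rt$meta$rescale_intercept, -1024)
  # invertibility: HU -> stored reproduces the stored integers exactly
  stored <- (rt$image$pixels - rt$meta$rescale_intercept) / rt$meta$rescale_slope
  expect_identical(stored, round(stored))
  expect_equal(stored[16, 16], 1124)
})

test_that("non-unit rescale slopes are applied", {
  hu <- matrix(seq(-100, 200, length.out = 1024), 32, 32)
  hu <- round(hu / 0.5) * 0.5  # representable at slope 0.5
  img <- ct_image(hu, spacing_mm = 1)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, path, rescale_slope = 0.5, rescale_intercept = -1000)
  expect_equal(read_dicom_slice(path)$image$pixels, hu)
})

test_that("series loading sorts by slice position and rejects mixed shapes", {
  dir <- withr::local_tempdir()
  a <- ct_image(matrix(1, 24, 24), spacing_mm = 1, id = "a")
  b <- ct_image(matrix(2, 24, 24), spacing_mm = 1, id = "b")
  # file names sort a < b, but z positions reverse that
  write_dicom_slice(a, file.path(dir, "a.dcm"), instance_number = 2, position = c(0, 0, 10))
  write_dicom_slice(b, file.path(dir, "b.dcm"), instance_number = 1, position = c(0, 0, 5))
  series <- load_dicom_series(dir)
  expect_length(series, 2)
  expect_equal(series[[1]]$image$pixels[1, 1], 2)
  expect_equal(series[[2]]$image$pixels[1, 1], 1)

  write_dicom_slice(ct_image(matrix(0, 16, 16), spacing_mm = 1),
                    file.path(dir, "c.dcm"), instance_number = 3)
  expect_error(load_dicom_series(dir), "mixed slice shapes")
})

test_that("missing required tags raise errors naming the tag", {
  # hand-assemble a file without PixelSpacing
  img <- ct_image(matrix(0, 16, 16), spacing_mm = 1)
  pix <- writeBin(as.integer(t(img$pixels + 1024)), raw(), size = 2, endian = "little")
  meta_body <- c(ctiq:::dcm_element(0x0002, 0x0010, "UI", ctiq:::TS_EXPLICIT_LE))
  bytes <- c(
    raw(128), charToRaw("DICM"),
    ctiq:::dcm_element(0x0002, 0x0000, "UL", ctiq:::uint32_raw(length(meta_body))),
    meta_body,
    ctiq:::dcm_element(0x0028, 0x0010, "US", 16L),
    ctiq:::dcm_element(0x0028, 0x0011, "US", 16L),
    ctiq:::dcm_element(0x0028, 0x0103, "US", 1L),
    ctiq:::dcm_element(0x0028, 0x1052, "DS", "-1024"),
    ctiq:::dcm_element(0x0028, 0x1053, "DS", "1"),
    ctiq:::dcm_element(0x7fe0, 0x0010, "OW", pix)
  )
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(bytes, path)
  expect_error(read_dicom_slice(path), "PixelSpacing")
})

test_that("an independent DICOM reader agrees with what we write", {
  hu <- matrix(round(rnorm(32 * 32, 100, 20)), 32, 32)
  img <- ct_image(hu, spacing_mm = c(0.7, 0.7))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(img, path)
  out <- system2("python", c("-c", shQuote(paste(
    "import sys, pydicom;",
    "d = pydicom.dcmread(sys.argv[1]);",
    "a = d.pixel_array * float(d.RescaleSlope) + float(d.RescaleIntercept);",
    "print(d.Rows, d.Columns, float(d.PixelSpacing[0]), a[0, 0], a.mean())"
  )), shQuote(path)), stdout = TRUE)
  vals <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(vals[1:2], c(32, 32))
  expect_equal(vals[3], 0.7)
  expect_equal(vals[4], hu[1, 1])
  expect_equal(vals[5], mean(hu), tolerance = 1e-10)
})

test_that("phantom fixtures round-trip through the DICOM layer", {
  b <- generate_phantom(small_phantom_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_phantom_fixture(b, dir, stem = "slice001")
  series <- load_dicom_series(dir)
  expect_length(series, 1)
  # HU quantization to integers is the only loss
  expect_lt(max(abs(series[[1]]$image$pixels - b$image$pixels)), 0.5 + 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "slice001_truth.json"))
  expect_equal(truth$truth_noise_sigma, b$truth_noise_sigma)
  line <- read_edge_line(file.path(dir, "slice001_edge.csv"))
  expect_equal(unclass(line), unclass(b$truth_edge_line), ignore_attr = TRUE)
})
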