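test_that("planar DICOM round trip preserves integer counts bit-for-bit", {
  img <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                            seed = 5))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  back <- read_planar(f)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$pixel_spacing_mm, img$pixel_spacing_mm)
  expect_equal(back$meta$device, "SIM")
})

test_that("rescale slope is applied on read", {
  # hand-built file: slope 2, stored value 50 must read back as 100
  stored <- matrix(50L, 4, 4)
  ds <- c(
    gammaQC:::dcm_element(0x28L, 0x10L, "US", gammaQC:::uint16_raw(4L)),
    gammaQC:::dcm_element(0x28L, 0x11L, "US", gammaQC:::uint16_raw(4L)),
    gammaQC:::dcm_element(0x28L, 0x30L, "DS",
                          gammaQC:::str_value("2.4\\2.4")),
    gammaQC:::dcm_element(0x28L, 0x1052L, "DS", gammaQC:::str_value("0")),
    gammaQC:::dcm_element(0x28L, 0x1053L, "DS", gammaQC:::str_value("2")),
    gammaQC:::dcm_element(0x7FE0L, 0x10L, "OW",
                          gammaQC:::uint16_raw(as.vector(t(stored)))))
  f0 <- withr::local_tempfile(fileext = ".dcm")
  con <- file(f0, "wb")
  writeBin(c(gammaQC:::dcm_meta_group("1.2.3"), ds), con)
  close(con)
  expect_equal(read_planar(f0)$pixels, matrix(100, 4, 4))

  # non-integral data round-trip through slope encoding within quantisation
  m <- matrix(seq(0, 1e5, length.out = 64^2), 64, 64)
  img <- planar_image(m, 2.4)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  back <- read_planar(f)
  slope <- max(m) / 65535
  expect_lt(max(abs(back$pixels - m)), 0.51 * slope)
})

test_that("a shuffled slice series is re-sorted by axial position", {
  vol <- constant_volume(n_slices = 6)
  for (i in seq_along(vol$slices)) vol$slices[[i]][1, 1] <- i
  dirp <- withr::local_tempdir()
  paths <- write_dicom(vol, dirp)
  back <- read_volume(sample(paths))
  expect_equal(length(back$slices), 6L)
  expect_equal(back$slice_positions_mm, vol$slice_positions_mm)
  expect_equal(sapply(back$slices, function(m) m[1, 1]), 1:6)
  expect_equal(back$slice_thickness_mm, 3.3)
})

test_that("multi-frame volumes read back identically to slice series", {
  vol <- constant_volume(n_slices = 4, n = 32)
  vol$slices <- lapply(1:4, function(i) matrix(i * 10, 32, 32))
  dirp <- withr::local_tempdir()
  f <- write_dicom(vol, dirp, multiframe = TRUE)
  back <- read_volume(f)
  expect_equal(length(back$slices), 4L)
  expect_identical(back$slices, vol$slices)
  expect_equal(back$slice_thickness_mm, vol$slice_thickness_mm)
})

test_that("series and geometry defects are refused", {
  v1 <- constant_volume(n = 32, n_slices = 2)
  v2 <- constant_volume(n = 48, n_slices = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_dicom(v1, d1)
  p2 <- write_dicom(v2, d2)
  expect_error(read_volume(c(p1[1], p2[1])), "mixed")

  # a gap in slice positions beyond tolerance is a series error
  v3 <- tomo_volume(replicate(3, matrix(1, 16, 16), simplify = FALSE),
                    3.3, 2, slice_positions_mm = c(0, 3.3, 13.2))
  d3 <- withr::local_tempdir()
  expect_error(read_volume(write_dicom(v3, d3)), "gapped|inconsistent")

  # non-square planar matrix is a geometry error
  m <- matrix(1:24, 4, 6)
  ds <- c(
    gammaQC:::dcm_element(0x28L, 0x10L, "US", gammaQC:::uint16_raw(4L)),
    gammaQC:::dcm_element(0x28L, 0x11L, "US", gammaQC:::uint16_raw(6L)),
    gammaQC:::dcm_element(0x28L, 0x30L, "DS",
                          gammaQC:::str_value("2.4\\2.4")),
    gammaQC:::dcm_element(0x7FE0L, 0x10L, "OW",
                          gammaQC:::uint16_raw(as.vector(t(m)))))
  f4 <- withr::local_tempfile(fileext = ".dcm")
  con <- file(f4, "wb")
  writeBin(c(gammaQC:::dcm_meta_group("1.2.3"), ds), con)
  close(con)
  expect_error(read_planar(f4), "non-square")
})

test_that("a file without pixel spacing is an error, never a 1 mm default", {
  # craft a dataset omitting the pixel-spacing element
  m <- matrix(1:16, 4, 4)
  ds <- c(
    gammaQC:::dcm_element(0x28L, 0x10L, "US", gammaQC:::uint16_raw(4L)),
    gammaQC:::dcm_element(0x28L, 0x11L, "US", gammaQC:::uint16_raw(4L)),
    gammaQC:::dcm_element(0x7FE0L, 0x10L, "OW",
                          gammaQC:::uint16_raw(as.vector(t(m)))))
  f <- withr::local_tempfile(fileext = ".dcm")
  con <- file(f, "wb")
  writeBin(c(gammaQC:::dcm_meta_group("1.2.3"), ds), con)
  close(con)
  expect_error(read_planar(f), "spacing")

  # and a dataset with no pixel data is a format error
  ds2 <- gammaQC:::dcm_element(0x28L, 0x10L, "US", gammaQC:::uint16_raw(4L))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  con <- file(f2, "wb")
  writeBin(c(gammaQC:::dcm_meta_group("1.2.3"), ds2), con)
  close(con)
  expect_error(read_planar(f2), "pixel data")
})

test_that("written files are conformant for an independent DICOM reader", {
  img <- simulate_bar_planar(sim_bar_config("bar1", 128,
                                            pixel_spacing_mm = 4.8,
                                            psf_fwhm_mm = 6, seed = 9))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "a = d.pixel_array.astype('float64')",
    "a = a * float(getattr(d, 'RescaleSlope', 1)) + float(getattr(d, 'RescaleIntercept', 0))",
    "print(d.Rows, d.Columns, float(d.PixelSpacing[0]), a.sum(), sep=',')"),
    py)
  out <- suppressWarnings(
    system2("python", c(py, f), stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  expect_equal(status, 0L)
  got <- as.numeric(strsplit(out[length(out)], ",")[[1]])
  expect_equal(got[1:2], c(128, 128))
  expect_equal(got[3], 4.8)
  expect_equal(got[4], sum(img$pixels))
})
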