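center0 <- list(x_mm = 0, y_mm = 0)

test_that("bar ROIs land at the template's printed offsets", {
  r1 <- place_bar_rois(center0, bar_template("bar1"))
  expect_equal(nrow(r1), 4L)
  expect_setequal(paste(r1$x_mm, r1$y_mm),
                  c("134 104", "-134 104", "-134 -104", "134 -104"))
  expect_true(all(r1$diameter_mm == 132))
  expect_equal(sort(r1$bar_width_mm), c(2.0, 2.5, 3.0, 3.5))

  r3 <- place_bar_rois(center0, bar_template("bar3"))
  expect_setequal(paste(r3$x_mm, r3$y_mm),
                  c("106 106", "-106 106", "-106 -106", "106 -106"))

  # a displaced centre pushes an ROI off a 256 x 2.4 mm image
  expect_error(
    place_bar_rois(list(x_mm = 300, y_mm = 0), bar_template("bar1"),
                   image_dim = c(256, 256), pixel_spacing_mm = 2.4),
    "placement error")
})

test_that("ACR section ROI sets match the template geometry", {
  tpl <- acr_template()
  sph <- place_acr_rois(center0, tpl, "spheres")
  expect_equal(nrow(sph), 7L)
  bg <- sph[sph$label == "background", ]
  expect_equal(c(bg$x_mm, bg$y_mm, bg$diameter_mm), c(0, 0, 69.2))
  # smallest sphere at 12 o'clock on the ring
  small <- sph[which.min(sph$object_size_mm), ]
  expect_equal(c(small$x_mm, small$y_mm), c(0, tpl$sphere_ring_radius_mm),
               tolerance = 1e-9)
  # all sphere ROIs on the ring, 60 degrees apart
  rr <- sqrt(sph$x_mm[-1]^2 + sph$y_mm[-1]^2)
  expect_equal(rr, rep(tpl$sphere_ring_radius_mm, 6))

  rods <- place_acr_rois(center0, tpl, "rods")
  expect_equal(nrow(rods), 6L)
  expect_equal(rods$length_mm, rep(72, 6), tolerance = 1e-6)
  # each line is centred at the rod-row radius
  mid_r <- sqrt(((rods$x0_mm + rods$x1_mm) / 2)^2 +
                  ((rods$y0_mm + rods$y1_mm) / 2)^2)
  expect_equal(mid_r, rep(tpl$rod_row_radius_mm, 6), tolerance = 1e-9)

  unif <- place_acr_rois(center0, tpl, "uniformity")
  expect_equal(nrow(unif), 5L)
  expect_true(all(unif$diameter_mm == 50))
  expect_equal(sum(unif$label == "center"), 1L)
})

test_that("ROI placement is a pure function of centre and template", {
  a <- place_acr_rois(list(x_mm = 3.2, y_mm = -1.1), acr_template(), "rods")
  b <- place_acr_rois(list(x_mm = 3.2, y_mm = -1.1), acr_template(), "rods")
  expect_identical(a, b)
})

test_that("roi_stats matches a brute-force pixel loop", {
  set.seed(42)
  m <- matrix(rpois(60^2, 40), 60, 60)
  roi <- circular_roi(8, -12, 44, "test")
  got <- roi_stats(m, roi, pixel_spacing_mm = 2)
  ref <- brute_roi_stats(m, 8, -12, 44, 2)
  expect_equal(got$mean, ref$mean, tolerance = 1e-12)
  expect_equal(got$sd, ref$sd, tolerance = 1e-12)
  expect_identical(got$n, ref$n)
})

test_that("roi_stats basics: constants, pixel counts, checkerboards", {
  m7 <- matrix(7, 64, 64)
  st <- roi_stats(m7, circular_roi(0, 0, 100), pixel_spacing_mm = 2.4)
  expect_equal(st$mean, 7)
  expect_equal(st$sd, 0)

  # 132 mm ROI on 2.4 mm pixels samples ~ pi * (66/2.4)^2 pixels
  stn <- roi_stats(matrix(1, 128, 128), circular_roi(0, 0, 132),
                   pixel_spacing_mm = 2.4)
  expect_lt(abs(stn$n - pi * (66 / 2.4)^2) / (pi * (66 / 2.4)^2), 0.02)

  # checkerboard 0/2 centred on a pixel corner: colours balance exactly
  n <- 64
  cb <- 2 * outer(1:n, 1:n, function(r, c) (r + c) %% 2)
  roi <- circular_roi(0, 0, 40, "cb")   # a pixel-corner point
  st2 <- roi_stats(cb, roi, pixel_spacing_mm = 1)
  expect_equal(st2$mean, 1)
  expect_equal(st2$sd, 1)

  expect_error(roi_stats(m7, circular_roi(0, 0, 3), pixel_spacing_mm = 2.4),
               "sampling error")
})

test_that("roi_stats is invariant under joint image/ROI translation", {
  set.seed(7)
  base <- matrix(rpois(40^2, 30), 40, 40)
  big <- matrix(0, 80, 80)
  big[21:60, 21:60] <- base
  shifted <- matrix(0, 80, 80)
  shifted[26:65, 31:70] <- base
  s1 <- roi_stats(big, circular_roi(0, 0, 30), pixel_spacing_mm = 1)
  # shift: +10 columns -> x + 10; +5 rows -> y - 5
  s2 <- roi_stats(shifted, circular_roi(10, -5, 30), pixel_spacing_mm = 1)
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  expect_identical(s1$n, s2$n)
})

test_that("total sampled counts are conserved under quadrant relabeling", {
  img <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                            seed = 3))
  tpl1 <- bar_template("bar1")
  tpl2 <- bar_template("bar1")
  tpl2$quadrant_map$bar_width_mm <- rev(tpl2$quadrant_map$bar_width_mm)
  tot <- function(tpl) {
    rois <- place_bar_rois(center0, tpl)
    sum(vapply(seq_len(4), function(i) {
      st <- roi_stats(img, rois[i, ])
      st$mean * st$n
    }, numeric(1)))
  }
  expect_equal(tot(tpl1), tot(tpl2))
})

test_that("line profiles interpolate bilinearly", {
  m <- matrix(5, 32, 32)
  prof <- line_profile(m, line_roi(-10, 0, 10, 0), step_mm = 0.5,
                       pixel_spacing_mm = 2)
  expect_equal(length(prof), floor(20 / 0.5) + 1)
  expect_equal(prof, rep(5, length(prof)))

  # linear ramp along x -> arithmetic sequence
  ramp <- matrix(rep(1:32, each = 32), 32, 32)   # column j has value j
  pr <- line_profile(ramp, line_roi(-12, 3, 12, 3), step_mm = 1,
                     pixel_spacing_mm = 2)
  expect_equal(diff(pr), rep(0.5, length(pr) - 1), tolerance = 1e-12)

  expect_error(line_profile(m, line_roi(0, 0, 10, 0), step_mm = 0,
                            pixel_spacing_mm = 2), "parameter error")
  expect_error(line_profile(m, line_roi(0, 0, 100, 0), step_mm = 1,
                            pixel_spacing_mm = 2), "placement error")
})

test_that("a sampled sinusoid image reproduces the analytic profile", {
  n <- 128
  sp <- 1
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  m <- matrix(rep(100 + 30 * sin(2 * pi * xs / 24), each = n), n, n)
  pr <- line_profile(m, line_roi(-36, 0, 36, 0), step_mm = sp / 4,
                     pixel_spacing_mm = sp)
  t <- seq(-36, 36, by = sp / 4)
  ref <- 100 + 30 * sin(2 * pi * t / 24)
  # bilinear sampling error under 1% of amplitude at quarter-pixel steps
  expect_lt(max(abs(pr - ref)), 0.01 * 30)
})
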