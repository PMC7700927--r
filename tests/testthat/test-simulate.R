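test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                          seed = 31))
  b <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                          seed = 31))
  expect_identical(a$pixels, b$pixels)
  c1 <- simulate_acr_volume(sim_acr_config(seed = 31))
  c2 <- simulate_acr_volume(sim_acr_config(seed = 31))
  expect_identical(c1$slices, c2$slices)
  # different seeds differ
  d <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                          seed = 32))
  expect_false(identical(a$pixels, d$pixels))
})

test_that("planar counts are conserved in expectation and realization", {
  img0 <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                             noise = "none"))
  expect_equal(sum(img0$pixels), 5e6, tolerance = 1e-9)
  img <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 4,
                                            seed = 44))
  expect_lt(abs(sum(img$pixels) - 5e6), 5 * sqrt(5e6))
})

test_that("unblurred bar patterns are binary with SD equal to the mean", {
  img <- simulate_bar_planar(sim_bar_config("bar1", 1024,
                                            pixel_spacing_mm = 0.5,
                                            psf_fwhm_mm = 0, noise = "none"))
  vals <- unique(as.vector(img$pixels))
  expect_lte(length(vals), 2L)            # background 0 and one hot level
  rois <- place_bar_rois(list(x_mm = 0, y_mm = 0), bar_template("bar1"))
  for (i in 1:4) {
    st <- roi_stats(img, rois[i, ])
    expect_equal(st$sd / st$mean, 1, tolerance = 0.03)
  }
})

test_that("heavy blur drives quadrant contrast and MTF towards zero", {
  img <- simulate_bar_planar(sim_bar_config("bar1", 256, psf_fwhm_mm = 25,
                                            noise = "none"))
  res <- suppressWarnings(
    analyze_bar_image(img, bar_template("bar1"), poisson_correct = FALSE))
  # residual variance is the blurred phantom edge inside the ROI, not bars
  expect_lt(max(res$points$mtf), 0.02)
})

test_that("aliasing guards reject unresolvable geometry", {
  expect_error(
    simulate_bar_planar(sim_bar_config("bar1", 64, psf_fwhm_mm = 0,
                                       noise = "none")),
    "aliasing error")
})

test_that("unblurred ACR slices realise the cold contrasts exactly", {
  cfg <- sim_acr_config(recon_fwhm_mm = 0, noise = "none",
                        sphere_contrast = 0.6, rod_contrast = 0.6)
  vol <- simulate_acr_volume(cfg)
  gt <- attr(vol, "ground_truth")
  sl <- vol$slices[[gt$sphere_center_slice]]
  sp <- vol$pixel_spacing_mm[1]
  xs <- (seq_len(128) - 64.5) * sp
  ys <- (64.5 - seq_len(128)) * sp
  bg <- gt$background
  # pixels strictly inside the largest sphere's minimal cross-section over
  # the slice-thickness window are exactly background * (1 - contrast)
  big <- gt$spheres[which.max(gt$spheres$diameter_mm), ]
  rad_min <- sqrt((big$diameter_mm / 2)^2 - (vol$slice_thickness_mm / 2)^2)
  inside <- outer((ys - big$y_mm)^2, (xs - big$x_mm)^2, `+`) <
    (rad_min - sp)^2
  expect_true(any(inside))
  expect_equal(unique(sl[inside]), bg * (1 - 0.6), tolerance = 1e-9)
  # and far-background pixels are exactly the background level
  far <- outer(ys^2, xs^2, `+`) < 20^2
  expect_equal(unique(sl[far]), bg, tolerance = 1e-9)
})

test_that("sphere cross-sections follow the circle-sphere intersection", {
  vol <- simulate_acr_volume(sim_acr_config(recon_fwhm_mm = 0,
                                            noise = "none"))
  gt <- attr(vol, "ground_truth")
  expect_true(gt$sphere_center_slice %in% gt$sections$spheres)
  s <- gt$spheres[which.max(gt$spheres$diameter_mm), ]
  r <- s$diameter_mm / 2
  tt <- vol$slice_thickness_mm
  sp <- vol$pixel_spacing_mm[1]
  xs <- (seq_len(128) - 64.5) * sp
  ys <- (64.5 - seq_len(128)) * sp
  r_xy <- sqrt(outer((ys - s$y_mm)^2, (xs - s$x_mm)^2, `+`))
  for (k in c(1, 2)) {                    # slices offset from the centre
    d <- k * tt
    sl <- vol$slices[[gt$sphere_center_slice + k]]
    rho_in <- sqrt(max(r^2 - (abs(d) + tt / 2)^2, 0))   # cold everywhere
    rho_out <- sqrt(max(r^2 - (abs(d) - tt / 2)^2, 0))  # cold vanishes
    if (rho_in > sp) {
      expect_true(all(sl[r_xy < rho_in - sp] == 0))
    }
    expect_true(all(sl[r_xy > rho_out + sp & r_xy < r + 15] ==
                      gt$background))
  }
})

test_that("centre depression and ring artifacts are injected as configured", {
  tpl <- acr_template()
  vol <- simulate_acr_volume(sim_acr_config(center_depression_fraction = 0.1,
                                            noise = "none"))
  r <- analyze_uniformity(vol, tpl, 5)
  # flat-bowl depression: peripheral ROIs see none of it, centre all of it,
  # so each deviation is +100 * cd / (1 - cd) within one percentage point
  expect_lt(max(abs(r$peripheral$percent_deviation - 100 * 0.1 / 0.9)), 1)

  ring <- simulate_acr_volume(sim_acr_config(
    ring_artifact = list(radius_mm = 40, amplitude = 0.2, width_mm = 4),
    recon_fwhm_mm = 0, noise = "none"))
  sl <- ring$slices[[3]]
  flat <- simulate_acr_volume(sim_acr_config(recon_fwhm_mm = 0,
                                             noise = "none"))$slices[[3]]
  ratio <- sl / pmax(flat, 1e-9)
  sp <- ring$pixel_spacing_mm[1]
  xs <- (seq_len(128) - 64.5) * sp
  rr <- sqrt(outer(((64.5 - seq_len(128)) * sp)^2, xs^2, `+`))
  on_ring <- abs(rr - 40) < 2
  off_ring <- rr < 20
  expect_gt(mean(ratio[on_ring]), 1.1)
  expect_equal(mean(ratio[off_ring]), 1, tolerance = 0.01)
})

test_that("uniformity section of a clean simulation reads near zero", {
  vol <- simulate_acr_volume(sim_acr_config(noise = "none"))
  r <- analyze_uniformity(vol, acr_template(), 6)
  expect_lt(max(abs(r$peripheral$percent_deviation)), 0.5)
})
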