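test_that("sphere CNR follows the background-noise formula and sign", {
  bg <- list(mean = 100, sd = 10, n = 500)
  expect_equal(sphere_cnr(list(mean = 70, sd = 12, n = 60), bg), 3.0)
  expect_equal(sphere_cnr(list(mean = 100, sd = 9, n = 60), bg), 0)
  expect_equal(sphere_cnr(list(mean = 110, sd = 9, n = 60), bg), -1.0)
  expect_error(sphere_cnr(list(mean = 70, sd = 1, n = 60),
                          list(mean = 100, sd = 0, n = 500)),
               "degenerate-background")
  # pooled denominator alternative
  expect_equal(sphere_cnr(list(mean = 70, sd = 10, n = 60), bg,
                          denominator = "pooled"), 3.0)
})

test_that("rod modulation estimates sinusoid amplitude over mean", {
  t <- seq(0, 20 * pi, length.out = 400)
  expect_equal(rod_modulation(rep(80, 50)), 0)
  expect_lt(abs(rod_modulation(100 + 30 * sin(t)) - 0.30), 0.005)
  # linear drift is removed before the SD estimate
  drift <- 100 + 30 * sin(t) + 0.1 * seq_along(t)
  expect_lt(abs(rod_modulation(drift) - 0.30 * 100 / mean(drift)), 0.01)
  # peak-valley variant agrees on a clean sinusoid
  expect_lt(abs(rod_modulation(100 + 30 * sin(t), method = "peak_valley") -
                  0.30), 0.01)
  expect_error(rod_modulation(rep(0, 50)), "domain error")
  expect_error(rod_modulation(1:5), "at least 8")
})

test_that("modulation is clamped to the binary-profile ceiling", {
  spike <- c(rep(0.001, 20), 1000, rep(0.001, 20))
  expect_lte(rod_modulation(spike), sqrt(2))
})

test_that("uniformity percent deviation is exact on crafted slices", {
  tpl <- acr_template()
  vol <- constant_volume(value = 100, n = 128, n_slices = 3)
  r <- analyze_uniformity(vol, tpl, 2)
  expect_equal(r$peripheral$percent_deviation, rep(0, 4), tolerance = 1e-12)

  # depress the east ROI region to 95 -> -5% deviation there
  sl <- matrix(100, 128, 128)
  sp <- 4.8 / 1.45
  xs <- (seq_len(128) - 64.5) * sp
  ys <- (64.5 - seq_len(128)) * sp
  rgt <- tpl$uniformity_peripheral_radius_mm
  # a 30 mm-radius patch: covers the whole east ROI (radius 25) without
  # touching the central or the other peripheral ROIs
  east <- outer(ys^2, (xs - rgt)^2, `+`) < 30^2
  sl[east] <- 95
  vol2 <- tomo_volume(list(sl), 3.3, sp)
  r2 <- analyze_uniformity(vol2, tpl, 1)
  expect_equal(r2$peripheral$percent_deviation[r2$peripheral$position ==
                                                 "east"], -5.0)
  expect_equal(r2$peripheral$percent_deviation[r2$peripheral$position ==
                                                 "west"], 0)
  expect_match(r2$advisory, "visual")
})

test_that("all ACR metrics are invariant to global intensity scaling", {
  tpl <- acr_template()
  vol <- simulate_acr_volume(sim_acr_config(seed = 4))
  gt <- attr(vol, "ground_truth")
  scaled <- vol
  scaled$slices <- lapply(vol$slices, function(m) m * 7.5)
  s1 <- analyze_spheres(vol, tpl, gt$sphere_center_slice)
  s2 <- analyze_spheres(scaled, tpl, gt$sphere_center_slice)
  expect_equal(s1$spheres$cnr, s2$spheres$cnr, tolerance = 1e-9)
  r1 <- analyze_rods(vol, tpl, gt$sections$rods[3], aggregate = FALSE)
  r2 <- analyze_rods(scaled, tpl, gt$sections$rods[3], aggregate = FALSE)
  expect_equal(r1$sectors$modulation, r2$sectors$modulation,
               tolerance = 1e-9)
  u1 <- analyze_uniformity(vol, tpl, 3)
  u2 <- analyze_uniformity(scaled, tpl, 3)
  expect_equal(u1$peripheral$percent_deviation,
               u2$peripheral$percent_deviation, tolerance = 1e-9)
})

test_that("a slice far outside the spheres reads near-zero CNR", {
  tpl <- acr_template()
  vol <- simulate_acr_volume(sim_acr_config(seed = 6))
  gt <- attr(vol, "ground_truth")
  r <- analyze_spheres(vol, tpl, gt$sections$uniformity[2])
  expect_true(all(abs(r$spheres$cnr) < 0.5 * 3))  # noise-scale only
})

test_that("lesion size at the Rose threshold interpolates the 3 smallest spheres", {
  expect_equal(interpolate_threshold(c(15.9, 12.7, 9.5), rev(c(1, 3, 5)), 3),
               12.7)
  vol <- simulate_acr_volume(sim_acr_config(seed = 8))
  gt <- attr(vol, "ground_truth")
  r <- analyze_spheres(vol, acr_template(), gt$sphere_center_slice)
  small3 <- utils::tail(r$spheres, 3)
  expect_equal(r$lesion_size_at_cnr_mm,
               interpolate_threshold(small3$diameter_mm, small3$cnr, 3))
})

test_that("the rods aggregate is the mean over slices and needs 10 of them", {
  tpl <- acr_template()
  vol <- simulate_acr_volume(sim_acr_config(seed = 12))
  gt <- attr(vol, "ground_truth")
  # duplicate one slice ten times: aggregate equals the single-slice result
  s <- gt$sections$rods[4]
  rep_vol <- tomo_volume(rep(vol$slices[s], 10), vol$slice_thickness_mm,
                         vol$pixel_spacing_mm)
  agg <- analyze_rods(rep_vol, tpl, 1:10)
  single <- analyze_rods(rep_vol, tpl, 1, aggregate = FALSE)
  expect_equal(agg$sectors$modulation, single$sectors$modulation)

  expect_error(analyze_rods(vol, tpl, gt$sections$rods[1:7]),
               "exactly 10")
  expect_s3_class(analyze_rods(vol, tpl, gt$sections$rods[1:7],
                               allow_any_count = TRUE), "rod_result")
})

test_that("aggregate modulation decreases with rod size on simulated volumes", {
  # noise-free: the blur ground truth orders every sector strictly
  vol0 <- simulate_acr_volume(sim_acr_config(noise = "none"))
  gt0 <- attr(vol0, "ground_truth")
  r0 <- analyze_rods(vol0, acr_template(), gt0$sections$rods[3:12])
  expect_true(all(diff(r0$sectors$modulation) < 0))

  # with counting noise the resolvable sectors still order strictly; the
  # smallest rods sit at the noise floor and are only bounded above
  vol <- simulate_acr_volume(sim_acr_config(seed = 14))
  gt <- attr(vol, "ground_truth")
  r <- analyze_rods(vol, acr_template(), gt$sections$rods[3:12])
  expect_true(all(diff(r$sectors$modulation[1:4]) < 0))
  expect_lt(max(r$sectors$modulation[5:6]), r$sectors$modulation[4] + 0.02)
  expect_named(r$rod_size_at_modulation_mm,
               paste0("modulation_", c(0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5)))
  # hand-checked bracket: sector modulations falling 0.5..0.1 at the
  # standard rod sizes cross 0.25 at 8.7 mm
  expect_equal(interpolate_threshold(c(12.7, 11.1, 9.5, 7.9, 6.4),
                                     c(0.5, 0.4, 0.3, 0.2, 0.1), 0.25), 8.7)
})

test_that("slice sweeps tabulate metrics per slice", {
  vol <- constant_volume(value = 50, n_slices = 4)
  sw <- slice_sweep(vol, acr_template(), "uniformity", 1:4)
  expect_s3_class(sw, "slice_sweep")
  expect_equal(unique(sw$value), 0)
  expect_equal(nrow(sw), 16L)
  expect_error(slice_sweep(vol, acr_template(), "rods", integer(0)),
               "empty")
})
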