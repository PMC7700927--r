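#' Simulation configuration for a planar bar-phantom image
#'
#' Defaults reproduce the conditions of a routine extrinsic bar-phantom
#' acquisition: Co-57 sheet source, 5e6 total counts, LEHR collimator-scale
#' blur, and a field of view of 614.4 mm so that a 256 matrix gives 2.4 mm
#' pixels and a 512 matrix 1.2 mm pixels (same physical field at both sizes).
#'
#' The blurred phantom is rendered analytically: each quadrant is a separable
#' product of a 1-D bar pattern and a 1-D window, so its Gaussian-blurred
#' image is an outer product of error-function profiles evaluated at the
#' pixel centres -- there is no rasterisation or aliasing error at any matrix
#' size. With `psf_fwhm_mm = 0` the pattern is sampled directly at the pixel
#' centres, so unblurred images are exactly binary.
#'
#' @param template `"bar1"`, `"bar2"` or `"bar3"`.
#' @param matrix_size Square acquisition matrix (default 256).
#' @param pixel_spacing_mm Pixel size; default `614.4 / matrix_size`.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum (mm).
#' @param total_counts Expected total image counts (default 5e6).
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param gaussian_sigma SD for `noise = "gaussian"` (counts).
#' @param phantom_offset_mm Length-2 (x, y) translation of the phantom.
#' @param oversample Unused by the analytic bar renderer; kept for config
#'   symmetry with [sim_acr_config()].
#' @param seed Integer seed; every output is bit-reproducible given the seed.
#' @return A list of class `sim_bar_config`.
#' @export
sim_bar_config <- function(template = "bar1", matrix_size = 256L,
                           pixel_spacing_mm = NULL, psf_fwhm_mm = 4,
                           total_counts = 5e6,
                           noise = c("poisson", "gaussian", "none"),
                           gaussian_sigma = 10, phantom_offset_mm = c(0, 0),
                           oversample = 5L, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- 614.4 / matrix_size
  stopifnot(psf_fwhm_mm >= 0, total_counts > 0, oversample %% 2 == 1)
  structure(list(template = template, matrix_size = as.integer(matrix_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 psf_fwhm_mm = psf_fwhm_mm, total_counts = total_counts,
                 noise = noise, gaussian_sigma = gaussian_sigma,
                 phantom_offset_mm = rep_len(phantom_offset_mm, 2L),
                 oversample = as.integer(oversample), seed = as.integer(seed)),
            class = "sim_bar_config")
}

# phantom outline half-extents (mm); sized so every quadrant ROI sits well
# inside the lead-bar region even under a few mm of blur
bar_outline_half <- function(template) {
  if (template$shape == "square") c(185, 185) else c(214, 182)
}

# Exact Gaussian blur via the FFT: multiplies the spectrum by the analytic
# Gaussian transfer function exp(-2 pi^2 sigma^2 f^2), so the simulated PSF
# has no kernel-truncation error (a truncated spatial kernel under-attenuates
# exactly where the MTF estimate is smallest). Boundary is periodic; phantoms
# keep a generous margin to the field edge.
gaussian_blur_fft <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  n1 <- nrow(m)
  n2 <- ncol(m)
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  h <- outer(exp(-2 * pi^2 * sigma_px^2 * f1^2),
             exp(-2 * pi^2 * sigma_px^2 * f2^2))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / length(m)
}


# Exact Gaussian-blurred indicator of the interval [a, b], sampled at u.
blurred_box <- function(u, a, b, sigma) {
  if (sigma <= 0) return(as.numeric(u > a & u <= b))
  stats::pnorm((b - u) / sigma) - stats::pnorm((a - u) / sigma)
}

# Exact Gaussian-blurred bar pattern (bar width = gap width = w, gaps "hot",
# pattern anchored at `origin`) restricted to the window [a, b], sampled at u.
# The blurred image of each quadrant is separable, so the whole phantom is
# rendered from error functions with no rasterisation or aliasing error.
blurred_bars <- function(u, w, a, b, origin, sigma) {
  jr <- floor((a - origin) / (2 * w) - 1):ceiling((b - origin) / (2 * w) + 1)
  out <- numeric(length(u))
  for (j in jr) {
    lo <- max(origin + 2 * j * w, a)
    hi <- min(origin + (2 * j + 1) * w, b)
    if (hi <= lo) next
    out <- out + blurred_box(u, lo, hi, sigma)
  }
  out
}

#' Simulate a four-quadrant bar-phantom planar image
#'
#' Builds the binary bar pattern of the chosen template (bar width = gap
#' width; orientation alternating 90 degrees between adjacent quadrants, the
#' largest bars in the top-right quadrant), blurs it with the Gaussian PSF,
#' scales the expectation to `total_counts`, and applies counting noise.
#'
#' @param config A [sim_bar_config()].
#' @return A [planar_image()] with attribute `ground_truth`: the true centre,
#'   the quadrant table, the expected total, and the analytic noise-free
#'   SD response per quadrant (see [square_wave_sd_response()]).
#' @export
simulate_bar_planar <- function(config) {
  stopifnot(inherits(config, "sim_bar_config"))
  tpl <- bar_template(config$template)
  n <- config$matrix_size
  s <- config$pixel_spacing_mm
  if (min(tpl$bar_widths_mm) < 2 * s && config$psf_fwhm_mm <= 0) {
    stop("aliasing error: smallest bar (", min(tpl$bar_widths_mm),
         " mm) is under 2 pixels at ", signif(s, 3),
         " mm with no blur; use a finer matrix", call. = FALSE)
  }
  sigma <- config$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  ox <- config$phantom_offset_mm[1]
  oy <- config$phantom_offset_mm[2]
  xs <- (seq_len(n) - (n + 1) / 2) * s             # by column
  ys <- ((n + 1) / 2 - seq_len(n)) * s             # by row (y up)
  half <- bar_outline_half(tpl)
  img <- matrix(0, n, n)
  qm <- tpl$quadrant_map
  for (k in seq_len(nrow(qm))) {
    xr <- if (qm$sx[k] > 0) c(ox, ox + half[1]) else c(ox - half[1], ox)
    yr <- if (qm$sy[k] > 0) c(oy, oy + half[2]) else c(oy - half[2], oy)
    w <- qm$bar_width_mm[k]
    # bars vertical (pattern along x) in Q1/Q3, horizontal in Q2/Q4
    if (qm$sx[k] == qm$sy[k]) {
      img <- img + outer(blurred_box(ys, yr[1], yr[2], sigma),
                         blurred_bars(xs, w, xr[1], xr[2], ox, sigma))
    } else {
      img <- img + outer(blurred_bars(ys, w, yr[1], yr[2], oy, sigma),
                         blurred_box(xs, xr[1], xr[2], sigma))
    }
  }
  img[img < 0] <- 0
  img <- img * config$total_counts / sum(img)
  img <- withr::with_seed(config$seed, switch(config$noise,
    poisson = matrix(as.numeric(stats::rpois(length(img), img)), n, n),
    gaussian = pmax(img + matrix(stats::rnorm(length(img),
                                              sd = config$gaussian_sigma),
                                 n, n), 0),
    none = img))
  gt <- list(
    center_mm = c(x = ox, y = oy),
    template = tpl$name,
    quadrants = dplyr::mutate(
      tibble::as_tibble(qm),
      noise_free_response = vapply(qm$bar_width_mm, square_wave_sd_response,
                                   numeric(1), fwhm_mm = config$psf_fwhm_mm)),
    expected_total = config$total_counts,
    config = config)
  out <- planar_image(img, s, meta = list(
    device = "SIM", datetime = "20260101T000000", isotope = "Co-57",
    collimator = "LEHR", phantom = tpl$name))
  attr(out, "ground_truth") <- gt
  out
}

#' Analytic SD response of a Gaussian-blurred square-wave bar pattern
#'
#' The value the SD-based MTF estimator converges to on a noise-free bar
#' pattern of the given width blurred by a Gaussian PSF: the population
#' SD/mean of one blurred square-wave period (computed from the exact
#' error-function profile), scaled by \eqn{\pi\sqrt{2}/4}. At zero blur this
#' is \eqn{\pi\sqrt{2}/4 \approx 1.1107}; for moderate blur it tracks the
#' Gaussian MTF at the bar frequency (square-wave harmonics enter as in
#' Coltman's synthesis).
#'
#' @param width_mm Bar width (= gap width) in mm.
#' @param fwhm_mm Gaussian PSF FWHM in mm.
#' @param n Samples per period for the numeric SD (default 4096).
#' @return Expected SD-based response (dimensionless).
#' @export
square_wave_sd_response <- function(width_mm, fwhm_mm, n = 4096L) {
  if (fwhm_mm <= 0) return(MTF_SCALE)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  w <- width_mm
  u <- (seq_len(n) - 0.5) / n * 2 * w
  jmax <- ceiling((6 * sigma + 2 * w) / (2 * w)) + 1L
  prof <- rep(0, n)
  for (j in -jmax:jmax) {
    prof <- prof + stats::pnorm((u - 2 * j * w) / sigma) -
      stats::pnorm((u - (2 * j + 1) * w) / sigma)
  }
  MTF_SCALE * sqrt(mean((prof - mean(prof))^2)) / mean(prof)
}

#' Simulation configuration for an ACR SPECT phantom volume
#'
#' Defaults follow a routine Tc-99m acquisition reconstructed at 128 x 128
#' with a 1.45 zoom (4.8 / 1.45 = 3.31 mm pixels) and 3.3-mm slices. The
#' volume holds three contiguous axial sections: uniformity, cold spheres
#' (centred mid-section, smallest sphere at 12 o'clock) and cold rods (six
#' sectors, hexagonal packing with centre spacing twice the rod diameter).
#' Spheres and rods are fully cold by default (`contrast = 1`).
#' Reconstruction-scale blur is modelled as an in-plane Gaussian; optional
#' centre depression (attenuation under-correction) and a ring artifact can
#' be injected.
#'
#' @param matrix_size Square slice matrix (default 128).
#' @param pixel_spacing_mm Pixel size (default 4.8 / 1.45).
#' @param slice_thickness_mm Slice thickness (default 3.3).
#' @param recon_fwhm_mm Reconstructed-resolution Gaussian FWHM (default 12,
#'   representative of LEHR FBP tomographic resolution).
#' @param mean_counts_per_pixel Expected background counts per pixel
#'   (default 250, the scale of a ~32M-count acquisition spread over the
#'   reconstructed cylinder).
#' @param sphere_contrast,rod_contrast Cold contrast in `[0, 1]`; 1 = fully
#'   cold.
#' @param center_depression_fraction Fractional depression at the phantom
#'   centre; the bowl is flat inside r = 30 mm and recovers smoothly to zero
#'   by r = 45 mm, so the central uniformity ROI sees the full depression and
#'   the peripheral ROIs none of it.
#' @param ring_artifact Optional `list(radius_mm, amplitude, width_mm)`
#'   multiplicative Gaussian-profile ring.
#' @param noise,gaussian_sigma As in [sim_bar_config()].
#' @param phantom_offset_mm (x, y) translation of the phantom axis.
#' @param section_slices Named integer vector: slices per section,
#'   `c(uniformity = 12, spheres = 12, rods = 14)`.
#' @param template The [acr_template()] whose physical geometry the simulated
#'   phantom realises.
#' @param oversample Odd sub-sampling factor for rasterisation.
#' @param seed Integer seed.
#' @return A list of class `sim_acr_config`.
#' @export
sim_acr_config <- function(matrix_size = 128L, pixel_spacing_mm = 4.8 / 1.45,
                           slice_thickness_mm = 3.3, recon_fwhm_mm = 12,
                           mean_counts_per_pixel = 250,
                           sphere_contrast = 1, rod_contrast = 1,
                           center_depression_fraction = 0,
                           ring_artifact = NULL,
                           noise = c("poisson", "gaussian", "none"),
                           gaussian_sigma = 10, phantom_offset_mm = c(0, 0),
                           section_slices = c(uniformity = 12L, spheres = 12L,
                                              rods = 14L),
                           template = acr_template(), oversample = 5L,
                           seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(sphere_contrast >= 0, sphere_contrast <= 1,
            rod_contrast >= 0, rod_contrast <= 1,
            recon_fwhm_mm >= 0, oversample %% 2 == 1,
            all(c("uniformity", "spheres", "rods") %in% names(section_slices)))
  structure(list(matrix_size = as.integer(matrix_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 recon_fwhm_mm = recon_fwhm_mm,
                 mean_counts_per_pixel = mean_counts_per_pixel,
                 sphere_contrast = sphere_contrast,
                 rod_contrast = rod_contrast,
                 center_depression_fraction = center_depression_fraction,
                 ring_artifact = ring_artifact, noise = noise,
                 gaussian_sigma = gaussian_sigma,
                 phantom_offset_mm = rep_len(phantom_offset_mm, 2L),
                 section_slices = section_slices, template = template,
                 oversample = as.integer(oversample), seed = as.integer(seed)),
            class = "sim_acr_config")
}

# hexagonally packed cold-rod centres for one sector, in the image frame.
# Bisector at angle `ang` (radians); rows of the lattice are perpendicular to
# the bisector with one row exactly at the outer rod-row radius.
rod_centers_sector <- function(ang, d, r_row, r_min = 25, r_max = 96) {
  row_step <- sqrt(3) * d                 # hex row spacing for pitch 2d
  us <- seq(r_row %% row_step, r_max, by = row_step)
  out <- list()
  for (u in us) {
    odd <- round((u - r_row) / row_step) %% 2 != 0
    vmax <- sqrt(max(r_max^2 - u^2, 0))
    vs <- seq(-ceiling(vmax / (2 * d)) * 2 * d, vmax, by = 2 * d) +
      if (odd) d else 0
    for (v in vs) {
      r <- sqrt(u^2 + v^2)
      if (u < r_min || r + d / 2 > r_max) next
      if (abs(atan2(v, u)) > (28 * pi / 180)) next  # stay inside the sector
      out[[length(out) + 1L]] <- c(u * cos(ang) - v * sin(ang),
                                   u * sin(ang) + v * cos(ang))
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

#' Simulate an ACR SPECT phantom volume
#'
#' @param config A [sim_acr_config()].
#' @return A [tomo_volume()] with attribute `ground_truth`: section slice
#'   ranges, sphere table (diameter, centre, per-slice in-plane radius is
#'   `sqrt(r^2 - dz^2)`), rod-centre table, the sphere-centre slice index,
#'   the true centre and the background level.
#' @export
simulate_acr_volume <- function(config) {
  stopifnot(inherits(config, "sim_acr_config"))
  tpl <- config$template
  n <- config$matrix_size
  s <- config$pixel_spacing_mm
  q <- config$oversample
  sf <- s / q
  if (min(tpl$rod_sector_diameters_mm) < 2 * sf) {
    stop("aliasing error: smallest rod under 2 raster samples; increase ",
         "oversample", call. = FALSE)
  }
  nf <- n * q
  ox <- config$phantom_offset_mm[1]
  oy <- config$phantom_offset_mm[2]
  xf <- (seq_len(nf) - (nf + 1) / 2) * sf
  yf <- ((nf + 1) / 2 - seq_len(nf)) * sf
  dx2 <- (xf - ox)^2
  dy2 <- (yf - oy)^2
  rr <- sqrt(outer(dy2, dx2, `+`))                  # radius from phantom axis
  disk <- rr <= tpl$interior_radius_mm
  radial <- rep(1, length(rr))
  dim(radial) <- dim(rr)
  cd <- config$center_depression_fraction
  if (cd != 0) {
    # flat bowl to 30 mm, cosine recovery complete at 45 mm
    taper <- ifelse(rr <= 30, 1,
                    ifelse(rr >= 45, 0, 0.5 * (1 + cos(pi * (rr - 30) / 15))))
    radial <- radial * (1 - cd * taper)
  }
  if (!is.null(config$ring_artifact)) {
    ra <- config$ring_artifact
    wdt <- ra$width_mm %||% 3
    radial <- radial * (1 + ra$amplitude * exp(-((rr - ra$radius_mm) / wdt)^2))
  }
  base <- disk * radial

  blur_decimate <- function(m) {
    if (config$recon_fwhm_mm > 0) {
      sigma_f <- config$recon_fwhm_mm / (2 * sqrt(2 * log(2))) / sf
      m <- gaussian_blur_fft(m, sigma_f)
    }
    if (q > 1L) {
      idx <- seq.int((q + 1L) / 2L, by = q, length.out = n)
      m <- m[idx, idx]
    }
    m[m < 0] <- 0
    m
  }

  ns <- config$section_slices
  n_slices <- sum(ns)
  z <- (seq_len(n_slices) - 1) * config$slice_thickness_mm
  sec <- list(
    uniformity = seq_len(ns[["uniformity"]]),
    spheres = ns[["uniformity"]] + seq_len(ns[["spheres"]]),
    rods = ns[["uniformity"]] + ns[["spheres"]] + seq_len(ns[["rods"]]))
  sphere_center_slice <- sec$spheres[ceiling(length(sec$spheres) / 2)]
  z_sphere <- z[sphere_center_slice]

  d_asc <- sort(tpl$sphere_diameters_mm)
  ring <- tpl$sphere_ring_radius_mm
  spheres <- purrr::imap_dfr(d_asc, function(d, k) {
    ang <- (90 - 60 * (k - 1)) * pi / 180
    tibble::tibble(diameter_mm = d, x_mm = ox + ring * cos(ang),
                   y_mm = oy + ring * sin(ang), z_mm = z_sphere)
  })

  rods <- purrr::imap_dfr(tpl$rod_sector_diameters_mm, function(d, k) {
    ang <- (90 - 60 * (k - 1)) * pi / 180
    ctr <- rod_centers_sector(ang, d, tpl$rod_row_radius_mm)
    if (!nrow(ctr)) return(tibble::tibble())
    tibble::tibble(rod_diameter_mm = d, x_mm = ox + ctr[, 1],
                   y_mm = oy + ctr[, 2])
  })

  paint_circles <- function(m, cx, cy, radius, factor) {
    for (i in seq_along(cx)) {
      cols <- which(abs(xf - cx[i]) <= radius[i])
      rows <- which(abs(yf - cy[i]) <= radius[i])
      if (!length(rows) || !length(cols)) next
      sub <- outer((yf[rows] - cy[i])^2, (xf[cols] - cx[i])^2, `+`) <
        radius[i]^2
      m[rows, cols][sub] <- m[rows, cols][sub] * factor
    }
    m
  }

  unif_slice <- blur_decimate(base)
  rods_fine <- paint_circles(base, rods$x_mm, rods$y_mm,
                             rods$rod_diameter_mm / 2,
                             1 - config$rod_contrast)
  rods_slice <- blur_decimate(rods_fine)

  # Spheres see genuine 3-D partial volume: the cold fraction at each pixel
  # is the slice-thickness integral of the sphere indicator, convolved with
  # an axial Gaussian of the reconstruction FWHM. Rod and uniformity sections
  # are axially uniform, so only the spheres need this.
  sigma_z <- if (config$recon_fwhm_mm > 0)
    config$recon_fwhm_mm / (2 * sqrt(2 * log(2))) else 0
  tt <- config$slice_thickness_mm
  paint_spheres <- function(m, z0) {
    for (j in seq_len(nrow(spheres))) {
      rad <- spheres$diameter_mm[j] / 2
      dzs <- if (sigma_z > 0) {
        seq(-(tt / 2 + 4 * sigma_z), tt / 2 + 4 * sigma_z, length.out = 41L)
      } else {
        seq(-tt / 2, tt / 2, length.out = 11L)
      }
      wk <- if (sigma_z > 0) {
        stats::pnorm((dzs + tt / 2) / sigma_z) -
          stats::pnorm((dzs - tt / 2) / sigma_z)
      } else {
        rep(1, length(dzs))
      }
      wk <- wk / sum(wk)
      rho <- sqrt(pmax(rad^2 - (z0 + dzs - spheres$z_mm[j])^2, 0))
      if (all(rho == 0)) next
      cols <- which(abs(xf - spheres$x_mm[j]) <= rad)
      rows <- which(abs(yf - spheres$y_mm[j]) <= rad)
      if (!length(rows) || !length(cols)) next
      r_xy <- sqrt(outer((yf[rows] - spheres$y_mm[j])^2,
                         (xf[cols] - spheres$x_mm[j])^2, `+`))
      ord <- order(rho)
      cw <- cumsum(wk[ord])
      idx <- findInterval(r_xy, rho[ord])
      frac <- 1 - ifelse(idx == 0L, 0, cw[pmax(idx, 1L)])
      m[rows, cols] <- m[rows, cols] *
        (1 - config$sphere_contrast * frac)
    }
    m
  }

  slices <- vector("list", n_slices)
  for (i in sec$uniformity) slices[[i]] <- unif_slice
  for (i in sec$rods) slices[[i]] <- rods_slice
  for (i in sec$spheres) {
    axial_reach <- max(spheres$diameter_mm) / 2 + tt / 2 + 4 * sigma_z
    slices[[i]] <- if (abs(z[i] - z_sphere) <= axial_reach) {
      blur_decimate(paint_spheres(base, z[i]))
    } else unif_slice
  }

  scale <- config$mean_counts_per_pixel
  slices <- withr::with_seed(config$seed, lapply(slices, function(m) {
    lambda <- m * scale
    switch(config$noise,
      poisson = matrix(as.numeric(stats::rpois(length(lambda), lambda)),
                       n, n),
      gaussian = pmax(lambda + matrix(stats::rnorm(length(lambda),
                                                   sd = config$gaussian_sigma),
                                      n, n), 0),
      none = lambda)
  }))

  gt <- list(center_mm = c(x = ox, y = oy), sections = sec,
             sphere_center_slice = sphere_center_slice, spheres = spheres,
             rods = rods, background = scale, config = config)
  out <- tomo_volume(slices, config$slice_thickness_mm, s,
                     slice_positions_mm = z,
                     meta = list(device = "SIM", datetime = "20260101T000000",
                                 isotope = "Tc-99m", collimator = "LEHR",
                                 phantom = "acr"))
  attr(out, "ground_truth") <- gt
  out
}
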