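# Shared fixtures: all built in code at test time.

# flood field: constant rectangle of `value` inside a zero frame
flood_image <- function(n = 80, spacing = 2, value = 100, half_mm = NULL,
                        offset_mm = c(0, 0)) {
  half_mm <- half_mm %||% (n * spacing * 0.35)
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  ys <- ((n + 1) / 2 - seq_len(n)) * spacing
  m <- outer(abs(ys - offset_mm[2]) <= half_mm,
             abs(xs - offset_mm[1]) <= half_mm) * value
  planar_image(m, spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-slice volume
constant_volume <- function(value = 100, n = 128, n_slices = 5,
                            spacing = 4.8 / 1.45, thickness = 3.3) {
  tomo_volume(replicate(n_slices, matrix(value, n, n), simplify = FALSE),
              thickness, spacing)
}

# independent brute-force ROI statistics: explicit loops over the pixel grid,
# pixel-centre membership, population SD
brute_roi_stats <- function(m, cx, cy, diameter, spacing) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  vals <- c()
  for (r in seq_len(n1)) {
    for (cc in seq_len(n2)) {
      x <- (cc - (n2 + 1) / 2) * spacing
      y <- ((n1 + 1) / 2 - r) * spacing
      if ((x - cx)^2 + (y - cy)^2 < (diameter / 2)^2) {
        vals <- c(vals, m[r, cc])
      }
    }
  }
  mu <- sum(vals) / length(vals)
  list(mean = mu, sd = sqrt(sum((vals - mu)^2) / length(vals)),
       n = length(vals))
}

# independent Coltman-style oracle for the SD response of a blurred square
# wave: Fourier series of the 0/1 bar pattern attenuated by the analytic
# Gaussian MTF, SD from the surviving harmonic amplitudes
fourier_square_wave_response <- function(width_mm, fwhm_mm, kmax = 199) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  f0 <- 1 / (2 * width_mm)
  ks <- seq(1, kmax, by = 2)
  amps <- (2 / (pi * ks)) * exp(-2 * pi^2 * sigma^2 * (ks * f0)^2)
  (pi * sqrt(2) / 4) * sqrt(sum(amps^2 / 2)) / 0.5
}
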