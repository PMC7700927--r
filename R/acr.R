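#' Sphere contrast-to-noise ratio
#'
#' CNR between a (cold) sphere ROI and the central background ROI:
#' \deqn{CNR = (\bar{B} - \bar{S}) / SD_B}
#' Positive for cold spheres; the sign is preserved so a hot artifact reads
#' negative. The background-noise denominator is the minimal adaptation of
#' the standard sphere contrast measurement; a pooled-SD denominator is
#' available via `denominator = "pooled"`.
#'
#' @param sphere,background `roi_stats` for the sphere and background ROIs.
#' @param denominator `"background"` (default) or `"pooled"`.
#' @return CNR value.
#' @export
sphere_cnr <- function(sphere, background,
                       denominator = c("background", "pooled")) {
  denominator <- match.arg(denominator)
  noise <- switch(denominator,
    background = background$sd,
    pooled = sqrt((background$sd^2 + sphere$sd^2) / 2))
  if (!is.finite(noise) || noise <= 0) {
    stop("degenerate-background error: background SD must be > 0",
         call. = FALSE)
  }
  (background$mean - sphere$mean) / noise
}

#' Modulation of a periodic line profile
#'
#' For a sinusoidal profile of amplitude A and mean m the modulation is A/m;
#' estimated here as \eqn{\sqrt{2}\,SD/\bar{x}} of the linearly detrended
#' profile (for a sinusoid, \eqn{SD = A/\sqrt{2}}), which is robust to the
#' sampling phase. The result is clamped to \eqn{[0, \sqrt 2]} (the binary
#' profile ceiling). A peak-valley estimator
#' \eqn{(\bar{P}-\bar{V})/(\bar{P}+\bar{V})} over detected local extrema is
#' available via `method = "peak_valley"`.
#'
#' @param profile Numeric vector of sampled counts (>= 8 samples, mean > 0).
#' @param method `"sd"` (default) or `"peak_valley"`.
#' @return Modulation value in `[0, sqrt(2)]`.
#' @export
rod_modulation <- function(profile, method = c("sd", "peak_valley")) {
  method <- match.arg(method)
  if (length(profile) < 8L) {
    stop("parameter error: profile needs at least 8 samples", call. = FALSE)
  }
  mu <- mean(profile)
  if (!is.finite(mu) || mu <= 0) {
    stop("domain error: profile mean must be positive", call. = FALSE)
  }
  if (method == "sd") {
    t <- seq_along(profile)
    detr <- stats::lm.fit(cbind(1, t), profile)$residuals
    mod <- sqrt(2) * sqrt(mean(detr^2)) / mu
  } else {
    d <- diff(profile)
    s <- sign(d)
    turn <- which(diff(s) != 0 & s[-length(s)] != 0) + 1L
    peaks <- profile[turn][s[turn - 1L] > 0]
    valleys <- profile[turn][s[turn - 1L] < 0]
    if (length(peaks) == 0L || length(valleys) == 0L) return(0)
    pb <- mean(peaks)
    vb <- mean(valleys)
    mod <- (pb - vb) / (pb + vb)
  }
  min(max(mod, 0), sqrt(2))
}

#' Analyse the spheres section of an ACR phantom slice
#'
#' Detects the phantom on the chosen slice (closing only, no blur), places
#' the background and six sphere ROIs, computes per-sphere CNR, and
#' interpolates the lesion size at the target CNR (default 3, the lower limit
#' of the Rose criterion) across the three smallest spheres.
#'
#' @param volume A [tomo_volume()].
#' @param template An [acr_template()].
#' @param slice Slice index to analyse.
#' @param params Optional configuration list.
#' @return Object of class `sphere_result`: `spheres` tibble
#'   (diameter_mm, cnr, mean, sd, n), `background` stats,
#'   `lesion_size_at_cnr_mm`, `cnr_threshold`, `slice_index`, `center`.
#' @export
analyze_spheres <- function(volume, template, slice, params = NULL) {
  stopifnot(inherits(volume, "tomo_volume"), inherits(template, "acr_template"))
  sl <- volume_slice(volume, slice)
  center <- detect_phantom(sl$pixels, sl$pixel_spacing_mm, params = params,
                           blur = FALSE)
  rois <- place_acr_rois(center, template, "spheres",
                         image_dim = dim(sl$pixels),
                         pixel_spacing_mm = sl$pixel_spacing_mm)
  bg <- roi_stats(sl$pixels, rois[rois$label == "background", ],
                  pixel_spacing_mm = sl$pixel_spacing_mm)
  sph_rois <- rois[rois$label != "background", ]
  spheres <- purrr::map_dfr(seq_len(nrow(sph_rois)), function(i) {
    st <- roi_stats(sl$pixels, sph_rois[i, ],
                    pixel_spacing_mm = sl$pixel_spacing_mm, min_pixels = 4L)
    tibble::tibble(diameter_mm = sph_rois$object_size_mm[i],
                   cnr = sphere_cnr(st, bg),
                   mean = st$mean, sd = st$sd, n = st$n)
  })
  spheres <- dplyr::arrange(spheres, dplyr::desc(diameter_mm))
  small3 <- dplyr::slice_tail(spheres, n = 3)      # three smallest spheres
  lesion <- interpolate_threshold(small3$diameter_mm, small3$cnr,
                                  template$cnr_threshold)
  structure(list(spheres = spheres, background = bg,
                 lesion_size_at_cnr_mm = lesion,
                 cnr_threshold = template$cnr_threshold,
                 slice_index = slice, center = center),
            class = "sphere_result")
}

#' Analyse the rods section of an ACR phantom
#'
#' For each requested slice: detect the phantom centre, place the six 72-mm
#' line ROIs over the outer rod rows, sample each profile at a quarter-pixel
#' step, and compute the per-sector modulation. In aggregate mode (the
#' default reporting mode) modulations are averaged across exactly ten slices
#' (analyze-then-average), and rod sizes at the configured modulation
#' thresholds are interpolated across the five largest rod sectors.
#'
#' @param volume A [tomo_volume()].
#' @param template An [acr_template()].
#' @param slices Integer vector of slice indices. Aggregate mode requires
#'   exactly `template$rod_aggregate_slices` (10) slices unless
#'   `allow_any_count = TRUE`.
#' @param aggregate Average across slices (default `TRUE` when more than one
#'   slice is given).
#' @param allow_any_count Override the 10-slice requirement.
#' @param method Modulation estimator, see [rod_modulation()].
#' @param params Optional configuration list.
#' @return Object of class `rod_result`: `per_slice` tibble (slice_index,
#'   rod_diameter_mm, modulation), `sectors` tibble (rod_diameter_mm,
#'   modulation - aggregated when requested), `rod_size_at_modulation_mm`
#'   (named by threshold), `aggregate`, `slices`.
#' @export
analyze_rods <- function(volume, template, slices,
                         aggregate = length(slices) > 1L,
                         allow_any_count = FALSE,
                         method = c("sd", "peak_valley"), params = NULL) {
  stopifnot(inherits(volume, "tomo_volume"), inherits(template, "acr_template"))
  method <- match.arg(method)
  if (aggregate && !allow_any_count &&
      length(slices) != template$rod_aggregate_slices) {
    stop("parameter error: aggregate rods analysis requires exactly ",
         template$rod_aggregate_slices, " slices (got ", length(slices),
         "); use allow_any_count = TRUE to override", call. = FALSE)
  }
  step <- volume$pixel_spacing_mm[2] / 4
  per_slice <- purrr::map_dfr(slices, function(s) {
    sl <- volume_slice(volume, s)
    center <- detect_phantom(sl$pixels, sl$pixel_spacing_mm, params = params,
                             blur = FALSE)
    rois <- place_acr_rois(center, template, "rods",
                           image_dim = dim(sl$pixels),
                           pixel_spacing_mm = sl$pixel_spacing_mm)
    purrr::map_dfr(seq_len(nrow(rois)), function(i) {
      prof <- line_profile(sl$pixels, rois[i, ], step_mm = step,
                           pixel_spacing_mm = sl$pixel_spacing_mm)
      tibble::tibble(slice_index = s,
                     rod_diameter_mm = rois$object_size_mm[i],
                     modulation = rod_modulation(prof, method = method))
    })
  })
  sectors <- per_slice |>
    dplyr::group_by(rod_diameter_mm) |>
    dplyr::summarise(modulation = mean(modulation), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(rod_diameter_mm))
  big5 <- dplyr::slice_head(sectors, n = 5)        # five largest rod sectors
  interp <- vapply(template$modulation_thresholds, function(th) {
    interpolate_threshold(big5$rod_diameter_mm, big5$modulation, th)
  }, numeric(1))
  names(interp) <- paste0("modulation_", template$modulation_thresholds)
  structure(list(per_slice = per_slice, sectors = sectors,
                 rod_size_at_modulation_mm = interp,
                 aggregate = aggregate, slices = slices),
            class = "rod_result")
}

#' Analyse the uniformity section of an ACR phantom slice
#'
#' Percent deviation of each of four peripheral 50-mm ROIs from the central
#' 50-mm ROI, the CT-style five-ROI uniformity test:
#' \deqn{\Delta_i = 100\,(\bar{x}_{p,i} - \bar{x}_c)/\bar{x}_c}
#'
#' Single-slice uniformity is reported with an advisory flag: on its own it
#' is not a sensitive artifact test and should be paired with visual review.
#'
#' @param volume A [tomo_volume()].
#' @param template An [acr_template()].
#' @param slice Slice index.
#' @param params Optional configuration list.
#' @return Object of class `uniformity_result`: `center_mean`, `peripheral`
#'   tibble (position, mean, percent_deviation), `slice_index`, `advisory`.
#' @export
analyze_uniformity <- function(volume, template, slice, params = NULL) {
  stopifnot(inherits(volume, "tomo_volume"), inherits(template, "acr_template"))
  sl <- volume_slice(volume, slice)
  center <- detect_phantom(sl$pixels, sl$pixel_spacing_mm, params = params,
                           blur = FALSE)
  rois <- place_acr_rois(center, template, "uniformity",
                         image_dim = dim(sl$pixels),
                         pixel_spacing_mm = sl$pixel_spacing_mm)
  stats <- purrr::map(seq_len(nrow(rois)), function(i) {
    roi_stats(sl$pixels, rois[i, ], pixel_spacing_mm = sl$pixel_spacing_mm)
  })
  names(stats) <- rois$label
  c_mean <- stats[["center"]]$mean
  if (!is.finite(c_mean) || c_mean <= 0) {
    stop("degenerate error: central ROI mean must be positive", call. = FALSE)
  }
  periph <- setdiff(rois$label, "center")
  p_means <- unname(vapply(periph, function(p) stats[[p]]$mean, numeric(1)))
  peripheral <- tibble::tibble(
    position = periph,
    mean = p_means,
    percent_deviation = 100 * (p_means - c_mean) / c_mean)
  structure(list(center_mean = c_mean, peripheral = peripheral,
                 slice_index = slice, center = center,
                 advisory = paste("single-slice uniformity is advisory only;",
                                  "confirm artifacts visually")),
            class = "uniformity_result")
}

#' Sweep a metric across all slices of a section
#'
#' Runs the section's analysis on every slice in `slices` and returns a long
#' table of metric values versus slice index, suitable for plotting
#' CNR-versus-slice (rise-peak-fall through the sphere centres) or
#' modulation-versus-slice variability.
#'
#' @param volume A [tomo_volume()].
#' @param template An [acr_template()].
#' @param section `"spheres"`, `"rods"` or `"uniformity"`.
#' @param slices Integer vector of slice indices (non-empty).
#' @param params Optional configuration list.
#' @return A tibble with class `slice_sweep`: columns `slice_index`,
#'   `section`, `object_size_mm` (or position), `metric_name`, `value`.
#' @export
slice_sweep <- function(volume, template,
                        section = c("spheres", "rods", "uniformity"),
                        slices, params = NULL) {
  section <- match.arg(section)
  if (length(slices) == 0L) {
    stop("parameter error: empty slice range", call. = FALSE)
  }
  out <- purrr::map_dfr(slices, function(s) {
    switch(section,
      spheres = {
        r <- analyze_spheres(volume, template, s, params = params)
        tibble::tibble(slice_index = s, section = section,
                       object_size_mm = r$spheres$diameter_mm,
                       metric_name = "cnr", value = r$spheres$cnr)
      },
      rods = {
        r <- analyze_rods(volume, template, s, aggregate = FALSE,
                          params = params)
        tibble::tibble(slice_index = s, section = section,
                       object_size_mm = r$sectors$rod_diameter_mm,
                       metric_name = "modulation", value = r$sectors$modulation)
      },
      uniformity = {
        r <- analyze_uniformity(volume, template, s, params = params)
        tibble::tibble(slice_index = s, section = section,
                       object_size_mm = NA_real_,
                       metric_name = paste0("percent_deviation_",
                                            r$peripheral$position),
                       value = r$peripheral$percent_deviation)
      })
  })
  class(out) <- c("slice_sweep", class(out))
  out
}

#' @export
print.sphere_result <- function(x, ...) {
  cat("<sphere_result> slice", x$slice_index, "\n")
  print(as.data.frame(x$spheres[, c("diameter_mm", "cnr")]), row.names = FALSE)
  cat(sprintf("  lesion size at CNR %.2g: %s mm\n", x$cnr_threshold,
              format(round(x$lesion_size_at_cnr_mm, 2))))
  invisible(x)
}

#' @export
print.rod_result <- function(x, ...) {
  cat("<rod_result>", if (x$aggregate) "aggregate over" else "slices",
      length(x$slices), "slice(s)\n")
  print(as.data.frame(x$sectors), row.names = FALSE)
  invisible(x)
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat("<uniformity_result> slice", x$slice_index,
      sprintf("(center mean %.4g)\n", x$center_mean))
  print(as.data.frame(x$peripheral[, c("position", "percent_deviation")]),
        row.names = FALSE)
  invisible(x)
}
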