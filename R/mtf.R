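#' Linear interpolation of object size at a metric threshold
#'
#' Scans adjacent (size, value) pairs from the largest size downwards, finds
#' the first pair whose values bracket the target, and linearly interpolates
#' size as a function of value. Shared by the bar MTF analysis (bar width at a
#' target MTF) and the ACR analysis (lesion size at a target CNR, rod size at
#' a target modulation). No extrapolation: a target outside the value range
#' returns `NA`.
#'
#' @param sizes_mm Strictly descending object sizes.
#' @param values Metric value per size.
#' @param target Threshold to solve for.
#' @return Interpolated size in mm, or `NA` when the target is not bracketed.
#' @examples
#' interpolate_threshold(c(3.5, 3.0), c(0.20, 0.10), 0.15)  # 3.25
#' @export
interpolate_threshold <- function(sizes_mm, values, target) {
  if (length(sizes_mm) != length(values)) {
    stop("parameter error: sizes and values must have equal length",
         call. = FALSE)
  }
  if (any(diff(sizes_mm) >= 0)) {
    stop("parameter error: sizes must be strictly descending", call. = FALSE)
  }
  for (i in seq_len(length(values) - 1L)) {
    v0 <- values[i]
    v1 <- values[i + 1L]
    if (is.na(v0) || is.na(v1)) next
    if ((target - v0) * (target - v1) <= 0) {
      if (v0 == v1) return(sizes_mm[i])           # flat bracket: exact knot
      f <- (target - v0) / (v1 - v0)
      return(sizes_mm[i] + f * (sizes_mm[i + 1L] - sizes_mm[i]))
    }
  }
  NA_real_
}

# Ceiling of the SD-based estimator: the response of an unblurred binary
# bar pattern (pi * sqrt(2) / 4).
MTF_SCALE <- pi * sqrt(2) / 4

#' SD-based MTF estimate from ROI statistics
#'
#' Estimates the modulation transfer at the bar frequency from the mean and
#' standard deviation of a circular ROI over a bar pattern. For count images
#' the Poisson variance contribution (variance equal to the mean) is
#' subtracted so a structure-free flood reads approximately zero:
#'
#' \deqn{MTF = \frac{\pi\sqrt{2}}{4}\,\frac{\sqrt{\max(SD^2 - \bar{x},\,0)}}{\bar{x}}}
#'
#' With `poisson_correct = FALSE` (noise-free or non-count data) the estimate
#' is \eqn{(\pi\sqrt{2}/4)\, SD/\bar{x}}. A negative variance excess is
#' clamped to zero (it occurs by chance at low counts) and flagged via the
#' `clamped` attribute. Estimates below 0.1 are below the method's validity
#' floor; callers annotate rather than discard them.
#'
#' @param stats A `roi_stats` (or list with `mean`, `sd`, `n`).
#' @param poisson_correct Subtract the Poisson variance term (default `TRUE`).
#' @return MTF estimate (>= 0) with attribute `clamped`.
#' @export
sd_mtf <- function(stats, poisson_correct = TRUE) {
  if (!is.finite(stats$mean) || stats$mean <= 0) {
    stop("domain error: ROI mean must be positive", call. = FALSE)
  }
  var_excess <- if (poisson_correct) stats$sd^2 - stats$mean else stats$sd^2
  clamped <- var_excess < 0
  mtf <- MTF_SCALE * sqrt(max(var_excess, 0)) / stats$mean
  attr(mtf, "clamped") <- clamped
  mtf
}

#' Analyse a four-quadrant bar phantom image
#'
#' Full pipeline: preprocess (closing + Gaussian blur), detect the phantom
#' centre, place the four quadrant ROIs on the raw counts, compute the
#' SD-based MTF per quadrant, and interpolate the bar width at the template's
#' threshold MTF values (over the largest three bar widths for the
#' rectangular phantoms, the largest four for the square phantom).
#'
#' A warning is issued if an ROI spans fewer than seven line-pair periods of
#' its quadrant's bars (the validity condition of the SD method).
#'
#' @param image A [planar_image()].
#' @param template A [bar_template()].
#' @param poisson_correct Subtract the Poisson term (default `TRUE`; turn off
#'   for noise-free synthetic images).
#' @param params Optional configuration list (detection parameters).
#' @return Object of class `mtf_result`: `points` (tibble: quadrant,
#'   bar_width_mm, frequency_lp_per_mm, mtf, below_validity, clamped),
#'   `interpolated_width_mm` (named by threshold), `center`, `template`.
#' @export
analyze_bar_image <- function(image, template, poisson_correct = TRUE,
                              params = NULL) {
  stopifnot(inherits(image, "planar_image"), inherits(template, "bar_template"))
  center <- detect_phantom(image, params = params, blur = TRUE)
  rois <- place_bar_rois(center, template, image_dim = dim(image$pixels),
                         pixel_spacing_mm = image$pixel_spacing_mm)
  points <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    n_periods <- template$roi_diameter_mm / (2 * roi$bar_width_mm)
    if (n_periods < 7) {
      warning("quadrant ", roi$label, ": ROI spans ", round(n_periods, 1),
              " line-pair periods (< 7); SD-based MTF may be unreliable",
              call. = FALSE)
    }
    st <- roi_stats(image, roi)
    mtf <- sd_mtf(st, poisson_correct = poisson_correct)
    tibble::tibble(
      quadrant = roi$label, bar_width_mm = roi$bar_width_mm,
      frequency_lp_per_mm = 1 / (2 * roi$bar_width_mm),
      mtf = as.numeric(mtf), mean = st$mean, sd = st$sd, n = st$n,
      below_validity = as.numeric(mtf) < 0.1,
      clamped = attr(mtf, "clamped"))
  })
  points <- dplyr::arrange(points, dplyr::desc(bar_width_mm))
  widths <- points$bar_width_mm[seq_len(template$n_interp)]
  vals <- points$mtf[seq_len(template$n_interp)]
  interp <- vapply(template$thresholds, function(th) {
    interpolate_threshold(widths, vals, th)
  }, numeric(1))
  names(interp) <- paste0("mtf_", template$thresholds)
  structure(list(points = points, interpolated_width_mm = interp,
                 thresholds = template$thresholds, center = center,
                 template = template$name),
            class = "mtf_result")
}

#' @export
print.mtf_result <- function(x, ...) {
  cat("<mtf_result> template", x$template, "\n")
  print(as.data.frame(x$points[, c("quadrant", "bar_width_mm", "mtf")]),
        row.names = FALSE)
  for (i in seq_along(x$interpolated_width_mm)) {
    cat(sprintf("  bar width at MTF %.2f: %s mm\n", x$thresholds[i],
                format(round(x$interpolated_width_mm[i], 2))))
  }
  invisible(x)
}

#' Control limits for a longitudinal metric history
#'
#' Sample mean and standard deviation of a metric history with mu +/- 3 sigma
#' limits, the standard statistical-process-control band for per-device QC
#' trending.
#'
#' @param history Numeric vector of past metric values.
#' @param min_history Minimum history length before limits are reported
#'   (default 10).
#' @return Object of class `control_chart`: `mu`, `sigma`, `lower`, `upper`,
#'   `range`, `n`, `ok` (FALSE with a `status` message when the history is too
#'   short).
#' @export
control_limits <- function(history, min_history = 10L) {
  history <- history[is.finite(history)]
  n <- length(history)
  if (n < min_history) {
    return(structure(list(ok = FALSE, n = n,
                          status = sprintf("insufficient history (%d < %d)",
                                           n, min_history),
                          mu = NA_real_, sigma = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          range = NA_real_),
                     class = "control_chart"))
  }
  mu <- mean(history)
  sigma <- stats::sd(history)
  structure(list(ok = TRUE, n = n, status = "ok", mu = mu, sigma = sigma,
                 lower = mu - 3 * sigma, upper = mu + 3 * sigma,
                 range = max(history) - min(history)),
            class = "control_chart")
}

#' Flag a value against control limits
#'
#' @param limits A `control_chart`.
#' @param value New metric value.
#' @return `TRUE` when the value falls outside the mu +/- 3 sigma band.
#' @export
outside_limits <- function(limits, value) {
  stopifnot(inherits(limits, "control_chart"))
  if (!limits$ok) stop("insufficient history: no limits available",
                       call. = FALSE)
  value < limits$lower || value > limits$upper
}

#' @export
print.control_chart <- function(x, ...) {
  if (!x$ok) cat("<control_chart>", x$status, "\n")
  else cat(sprintf("<control_chart> n %d, mu %.4g, sigma %.4g, limits [%.4g, %.4g]\n",
                   x$n, x$mu, x$sigma, x$lower, x$upper))
  invisible(x)
}
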