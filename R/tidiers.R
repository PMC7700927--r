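#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy bar-phantom MTF results
#'
#' @param x An `mtf_result`.
#' @param ... Unused.
#' @return One row per quadrant: `quadrant`, `bar_width_mm`,
#'   `frequency_lp_per_mm`, `mtf`, `below_validity`, `clamped`.
#' @export
tidy.mtf_result <- function(x, ...) x$points

#' @rdname tidy.mtf_result
#' @return For `glance()`: one row with the template, detected centre and the
#'   interpolated bar widths at each threshold MTF.
#' @export
glance.mtf_result <- function(x, ...) {
  out <- tibble::tibble(template = x$template,
                        center_x_mm = x$center$x_mm,
                        center_y_mm = x$center$y_mm)
  for (nm in names(x$interpolated_width_mm)) {
    out[[paste0("width_at_", nm)]] <- x$interpolated_width_mm[[nm]]
  }
  out
}

#' Tidy ACR sphere results
#'
#' @param x A `sphere_result`.
#' @param ... Unused.
#' @export
tidy.sphere_result <- function(x, ...) {
  dplyr::mutate(x$spheres, slice_index = x$slice_index)
}

#' @rdname tidy.sphere_result
#' @export
glance.sphere_result <- function(x, ...) {
  tibble::tibble(slice_index = x$slice_index,
                 background_mean = x$background$mean,
                 background_sd = x$background$sd,
                 cnr_threshold = x$cnr_threshold,
                 lesion_size_at_cnr_mm = x$lesion_size_at_cnr_mm)
}

#' Tidy ACR rod results
#'
#' @param x A `rod_result`.
#' @param ... Unused.
#' @return Per-slice sector modulations (long form).
#' @export
tidy.rod_result <- function(x, ...) x$per_slice

#' @rdname tidy.rod_result
#' @export
glance.rod_result <- function(x, ...) {
  out <- tibble::tibble(aggregate = x$aggregate, n_slices = length(x$slices))
  for (nm in names(x$rod_size_at_modulation_mm)) {
    out[[paste0("rod_size_at_", nm)]] <- x$rod_size_at_modulation_mm[[nm]]
  }
  out
}

#' Tidy uniformity results
#'
#' @param x A `uniformity_result`.
#' @param ... Unused.
#' @export
tidy.uniformity_result <- function(x, ...) {
  dplyr::mutate(x$peripheral, slice_index = x$slice_index,
                center_mean = x$center_mean)
}

#' MTF-versus-frequency plot
#'
#' @param object An `mtf_result`.
#' @param ... Unused.
#' @return A ggplot: MTF against spatial frequency (line pairs/mm), one point
#'   per quadrant, with the validity floor marked.
#' @export
autoplot.mtf_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = frequency_lp_per_mm, y = mtf)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = below_validity), size = 3) +
    ggplot2::geom_hline(yintercept = 0.1, linetype = "dotted") +
    ggplot2::labs(x = "spatial frequency (lp/mm)", y = "SD-based MTF",
                  shape = "below validity floor",
                  title = paste("Bar phantom MTF -", object$template)) +
    ggplot2::theme_minimal()
}

#' Metric-versus-slice plot for a section sweep
#'
#' @param object A `slice_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.slice_sweep <- function(object, ...) {
  df <- dplyr::mutate(object,
                      series = ifelse(is.na(object_size_mm), metric_name,
                                      paste0(object_size_mm, " mm")))
  ggplot2::ggplot(df, ggplot2::aes(x = slice_index, y = value,
                                   colour = series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "slice index", y = unique(df$metric_name)[1],
                  colour = NULL,
                  title = paste("Slice sweep -", unique(df$section)[1])) +
    ggplot2::theme_minimal()
}

#' Control-chart plot for a metric history
#'
#' @param object A numeric metric history.
#' @param limits Optional `control_chart`; computed from the history when
#'   omitted.
#' @param ... Unused.
#' @return A ggplot of the history with mu and mu +/- 3 sigma lines.
#' @export
plot_control_chart <- function(object, limits = NULL, ...) {
  limits <- limits %||% control_limits(object, min_history = 2L)
  df <- tibble::tibble(index = seq_along(object), value = object)
  p <- ggplot2::ggplot(df, ggplot2::aes(index, value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "acquisition", y = "metric",
                  title = "QC control chart") +
    ggplot2::theme_minimal()
  if (isTRUE(limits$ok)) {
    p <- p +
      ggplot2::geom_hline(yintercept = limits$mu, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = c(limits$lower, limits$upper),
                          linetype = "dotted", colour = "red")
  }
  p
}
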