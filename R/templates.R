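#' Four-quadrant bar phantom templates
#'
#' The three standard templates: two rectangular phantoms (`bar1`: 3.5, 3.0,
#' 2.5, 2.0 mm bars; `bar2`: 4.0, 3.5, 3.2, 2.5 mm) and one square phantom
#' (`bar3`: 6.4, 4.8, 4.0, 3.2 mm). Each template places one 132-mm circular
#' ROI per quadrant at fixed offsets from the detected phantom centre:
#' (+/-134, +/-104) mm for the rectangular phantoms and (+/-106, +/-106) mm
#' for the square one.
#'
#' The quadrant map assigns bar widths (descending) to quadrants starting at
#' (+x, +y) and proceeding counter-clockwise, matching the coached orientation
#' with the largest bars in the top right. Interpolation thresholds default to
#' MTF 0.15 and 0.1 over the largest three bar widths (`bar1`/`bar2`) and MTF
#' 0.5 and 0.25 over the largest four widths (`bar3`).
#'
#' @param name One of `"bar1"`, `"bar2"`, `"bar3"`.
#' @param config Optional geometry configuration list (see
#'   [read_geometry_config()]); its `bar_templates[[name]]` entry overrides the
#'   built-in defaults.
#' @return An object of class `bar_template`.
#' @examples
#' bar_template("bar1")$bar_widths_mm
#' @export
bar_template <- function(name = c("bar1", "bar2", "bar3"), config = NULL) {
  name <- match.arg(name)
  defaults <- list(
    bar1 = list(bar_widths_mm = c(3.5, 3.0, 2.5, 2.0),
                roi_offset_mm = c(134, 104), n_interp = 3L,
                thresholds = c(0.15, 0.1), shape = "rectangle"),
    bar2 = list(bar_widths_mm = c(4.0, 3.5, 3.2, 2.5),
                roi_offset_mm = c(134, 104), n_interp = 3L,
                thresholds = c(0.15, 0.1), shape = "rectangle"),
    bar3 = list(bar_widths_mm = c(6.4, 4.8, 4.0, 3.2),
                roi_offset_mm = c(106, 106), n_interp = 4L,
                thresholds = c(0.5, 0.25), shape = "square")
  )
  tpl <- defaults[[name]]
  if (!is.null(config$bar_templates[[name]])) {
    tpl <- utils::modifyList(tpl, config$bar_templates[[name]])
  }
  tpl$name <- name
  tpl$roi_diameter_mm <- tpl$roi_diameter_mm %||% 132
  # quadrant signs, counter-clockwise from (+x, +y); widths descending
  tpl$quadrant_map <- tpl$quadrant_map %||% data.frame(
    quadrant = c("Q1", "Q2", "Q3", "Q4"),
    sx = c(1, -1, -1, 1), sy = c(1, 1, -1, -1),
    bar_width_mm = sort(tpl$bar_widths_mm, decreasing = TRUE)
  )
  structure(tpl, class = "bar_template")
}

#' ACR SPECT phantom template
#'
#' Geometry for the three sections of an ACR/Jaszczak-style SPECT phantom:
#' cold spheres, cold rod sectors and the uniform region. Printed template
#' geometry: a 69.2-mm background ROI at the phantom centre for the spheres
#' section, a single 72-mm line ROI over the outer rod row of each sector, and
#' five 50-mm ROIs (centre + 4 peripheral) for uniformity. Sphere and rod
#' physical sizes and ring radii are phantom-datasheet values; the defaults
#' below describe the standard commercial phantom and should be confirmed
#' against the datasheet of the phantom in use (override via `config$acr`).
#'
#' @param config Optional geometry configuration list (see
#'   [read_geometry_config()]).
#' @return An object of class `acr_template`.
#' @export
acr_template <- function(config = NULL) {
  tpl <- list(
    interior_radius_mm = 108,
    background_roi_diameter_mm = 69.2,
    sphere_diameters_mm = c(31.8, 25.4, 19.1, 15.9, 12.7, 9.5),
    sphere_ring_radius_mm = 54,
    sphere_roi_scale = 1.0,        # ROI diameter = scale * sphere diameter
    rod_sector_diameters_mm = c(12.7, 11.1, 9.5, 7.9, 6.4, 4.8),
    rod_line_length_mm = 72,
    rod_row_radius_mm = 74,        # radius of the outer rod row
    uniformity_roi_diameter_mm = 50,
    uniformity_peripheral_radius_mm = NULL,   # default derived below
    cnr_threshold = 3,             # Rose-criterion lower limit
    modulation_thresholds = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5),
    rod_aggregate_slices = 10L
  )
  if (!is.null(config$acr)) tpl <- utils::modifyList(tpl, config$acr)
  if (is.null(tpl$uniformity_peripheral_radius_mm)) {
    tpl$uniformity_peripheral_radius_mm <-
      tpl$interior_radius_mm - 0.75 * tpl$uniformity_roi_diameter_mm
  }
  stopifnot(length(tpl$sphere_diameters_mm) == 6L,
            length(tpl$rod_sector_diameters_mm) == 6L)
  tpl$sphere_diameters_mm <- sort(tpl$sphere_diameters_mm, decreasing = TRUE)
  tpl$rod_sector_diameters_mm <- sort(tpl$rod_sector_diameters_mm,
                                      decreasing = TRUE)
  structure(tpl, class = "acr_template")
}

#' Read a geometry / analysis configuration file
#'
#' YAML file with optional top-level keys `bar_templates`, `acr`, `detection`
#' and `device_tags` (a user-editable mapping of DICOM tag names used to
#' identify devices, since tag selection is site policy, not fixed).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Detection parameter defaults
#'
#' @param config Optional configuration list; `config$detection` overrides.
#' @return List with `threshold_fraction`, `kernel_px`, `blur_sigma_px`,
#'   `min_area_mm2`.
#' @export
detection_params <- function(config = NULL) {
  p <- list(threshold_fraction = 0.10, kernel_px = 3L,
            blur_sigma_px = 1, min_area_mm2 = 2000)
  if (!is.null(config$detection)) p <- utils::modifyList(p, config$detection)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
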