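#' Flatten analysis results to the report schema
#'
#' One row per (device, datetime, phantom, section, slice, object size,
#' metric): the schema used by the CSV/JSON exports.
#'
#' @param result An `mtf_result`, `sphere_result`, `rod_result`,
#'   `uniformity_result` or `slice_sweep`.
#' @param device,datetime,phantom Identification columns.
#' @return A tibble with columns `device`, `datetime`, `phantom`, `section`,
#'   `slice_index`, `object_size_mm`, `metric_name`, `value`.
#' @export
report_rows <- function(result, device = "unknown", datetime = "",
                        phantom = "") {
  base <- function(section, slice_index, object_size_mm, metric_name, value) {
    tibble::tibble(device = device, datetime = datetime, phantom = phantom,
                   section = section, slice_index = slice_index,
                   object_size_mm = object_size_mm, metric_name = metric_name,
                   value = value)
  }
  if (inherits(result, "mtf_result")) {
    rows <- base("bar", NA_integer_, result$points$bar_width_mm, "mtf",
                 result$points$mtf)
    interp <- base("bar", NA_integer_, NA_real_,
                   paste0("bar_width_at_", names(result$interpolated_width_mm)),
                   unname(result$interpolated_width_mm))
    return(dplyr::bind_rows(rows, interp))
  }
  if (inherits(result, "sphere_result")) {
    rows <- base("spheres", result$slice_index, result$spheres$diameter_mm,
                 "cnr", result$spheres$cnr)
    interp <- base("spheres", result$slice_index, NA_real_,
                   sprintf("lesion_size_at_cnr_%g", result$cnr_threshold),
                   result$lesion_size_at_cnr_mm)
    return(dplyr::bind_rows(rows, interp))
  }
  if (inherits(result, "rod_result")) {
    rows <- base("rods", NA_integer_, result$sectors$rod_diameter_mm,
                 if (result$aggregate) "modulation_aggregate" else "modulation",
                 result$sectors$modulation)
    interp <- base("rods", NA_integer_, NA_real_,
                   paste0("rod_size_at_",
                          names(result$rod_size_at_modulation_mm)),
                   unname(result$rod_size_at_modulation_mm))
    return(dplyr::bind_rows(rows, interp))
  }
  if (inherits(result, "uniformity_result")) {
    return(base("uniformity", result$slice_index, NA_real_,
                paste0("percent_deviation_", result$peripheral$position),
                result$peripheral$percent_deviation))
  }
  if (inherits(result, "slice_sweep")) {
    return(base(result$section, result$slice_index, result$object_size_mm,
                result$metric_name, result$value))
  }
  stop("unsupported result type: ", paste(class(result), collapse = "/"),
       call. = FALSE)
}

#' Write a metric report
#'
#' @param results A result object (see [report_rows()]), a list of them, or a
#'   ready-made report tibble.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; both carry the same schema.
#' @param ... Passed to [report_rows()] (`device`, `datetime`, `phantom`).
#' @return Invisibly, the report tibble.
#' @export
write_report <- function(results, path, format = c("csv", "json"), ...) {
  format <- match.arg(format)
  rows <- if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else if (inherits(results, c("mtf_result", "sphere_result", "rod_result",
                                 "uniformity_result", "slice_sweep"))) {
    report_rows(results, ...)
  } else if (is.list(results)) {
    purrr::map_dfr(results, report_rows, ...)
  } else {
    stop("unsupported results object", call. = FALSE)
  }
  if (format == "csv") {
    readr::write_csv(rows, path)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(rows)
}

#' Read a metric report back
#'
#' @param path Report file written by [write_report()].
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return The report tibble.
#' @export
read_report <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      device = readr::col_character(),
                      datetime = readr::col_character(),
                      phantom = readr::col_character(),
                      section = readr::col_character(),
                      slice_index = readr::col_integer(),
                      object_size_mm = readr::col_double(),
                      metric_name = readr::col_character(),
                      value = readr::col_double()))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
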