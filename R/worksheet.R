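#' Build a QC worksheet entry
#'
#' A worksheet entry pairs the automated metrics for one acquisition with the
#' technologist's visual entries, ready for rule evaluation.
#'
#' @param device Device identifier.
#' @param datetime Acquisition datetime string.
#' @param phantom Phantom/template name.
#' @param automated Automated result object (e.g. an `mtf_result`), or a
#'   tibble of metrics.
#' @param visual_bar_mm Smallest visually resolvable bar width (mm), if
#'   entered.
#' @param visual_sphere_mm,visual_rod_mm Visual entries for the ACR sections.
#' @param uniformity_ok,artifact Logical visual flags.
#' @return A list of class `worksheet_entry`.
#' @export
worksheet_entry <- function(device, datetime, phantom, automated = NULL,
                            visual_bar_mm = NA_real_,
                            visual_sphere_mm = NA_real_,
                            visual_rod_mm = NA_real_,
                            uniformity_ok = NA, artifact = NA) {
  structure(list(device = device, datetime = datetime, phantom = phantom,
                 automated = automated, visual_bar_mm = visual_bar_mm,
                 visual_sphere_mm = visual_sphere_mm,
                 visual_rod_mm = visual_rod_mm,
                 uniformity_ok = uniformity_ok, artifact = artifact),
            class = "worksheet_entry")
}

#' Evaluate worksheet pass/fail rules
#'
#' Pure rule evaluation; identical inputs give identical status and reasons.
#' Two rule families are applied and labelled separately:
#'
#' * Visual rule: the entry fails when the visually resolvable bar width is
#'   strictly greater than 3.0 mm (the recommended "Satisfactory" criterion
#'   for extrinsic resolution; 3.0 mm itself passes).
#' * Automated rules: any per-bar MTF outside its mu +/- 3 sigma control
#'   limits (when limits exist) fails; an interpolated bar width at the
#'   configured MTF threshold (default 0.12) exceeding the configured size
#'   limit (default 3.0 mm) fails.
#'
#' @param entry A [worksheet_entry()] whose `automated` field is an
#'   `mtf_result` (required for the automated rules).
#' @param limits Optional named list of `control_chart` objects keyed by bar
#'   width (e.g. `"3.5"`).
#' @param thresholds List of rule settings: `visual_bar_limit_mm` (3.0),
#'   `interp_mtf` (0.12), `interp_width_limit_mm` (3.0).
#' @return List of class `worksheet_evaluation`: `status` ("pass"/"fail") and
#'   `reasons` (character; one string per triggered rule, empty on pass).
#' @export
evaluate_worksheet <- function(entry, limits = NULL,
                               thresholds = list()) {
  stopifnot(inherits(entry, "worksheet_entry"))
  th <- utils::modifyList(list(visual_bar_limit_mm = 3.0, interp_mtf = 0.12,
                               interp_width_limit_mm = 3.0), thresholds)
  reasons <- character(0)
  if (is.finite(entry$visual_bar_mm) &&
      entry$visual_bar_mm > th$visual_bar_limit_mm) {
    reasons <- c(reasons, sprintf(
      "visual: resolvable bar width %.2f mm > %.1f mm limit",
      entry$visual_bar_mm, th$visual_bar_limit_mm))
  }
  auto <- entry$automated
  if (is.null(auto)) {
    if (length(reasons) == 0 && !is.finite(entry$visual_bar_mm)) {
      stop("incomplete-entry error: no automated results and no visual entry",
           call. = FALSE)
    }
  } else if (inherits(auto, "mtf_result")) {
    if (!is.null(limits)) {
      for (i in seq_len(nrow(auto$points))) {
        key <- format(auto$points$bar_width_mm[i])
        lim <- limits[[key]]
        if (!is.null(lim) && lim$ok &&
            outside_limits(lim, auto$points$mtf[i])) {
          reasons <- c(reasons, sprintf(
            "automated: %.1f mm bar MTF %.3f outside limits [%.3f, %.3f]",
            auto$points$bar_width_mm[i], auto$points$mtf[i],
            lim$lower, lim$upper))
        }
      }
    }
    iw <- interpolate_threshold(
      auto$points$bar_width_mm, auto$points$mtf, th$interp_mtf)
    if (is.finite(iw) && iw > th$interp_width_limit_mm) {
      reasons <- c(reasons, sprintf(
        "automated: interpolated bar width %.2f mm at MTF %.2f exceeds %.1f mm",
        iw, th$interp_mtf, th$interp_width_limit_mm))
    }
  }
  structure(list(status = if (length(reasons)) "fail" else "pass",
                 reasons = reasons),
            class = "worksheet_evaluation")
}

#' @export
print.worksheet_evaluation <- function(x, ...) {
  cat("<worksheet_evaluation>", toupper(x$status), "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Append metrics to a longitudinal history store
#'
#' The store is an append-only CSV keyed by (device, metric, object size);
#' control limits are recomputed on demand from the store. A malformed store
#' is refused with a recovery hint rather than silently truncated.
#'
#' @param store Path to the history CSV (created if absent).
#' @param entry A [worksheet_entry()] whose `automated` field is an
#'   `mtf_result`, or a tibble with columns `metric`, `object_size_mm`,
#'   `value`.
#' @param min_history Minimum history per key before limits are reported.
#' @param include_below_validity Keep MTF values below the 0.1 validity floor
#'   in control-limit histories (default `FALSE`).
#' @return Invisibly, a tibble of per-key [control_limits()] summaries
#'   (device, metric, object_size_mm, n, mu, sigma, lower, upper, range).
#' @export
update_history <- function(store, entry, min_history = 10L,
                           include_below_validity = FALSE) {
  new_rows <- history_rows(entry, include_below_validity)
  old <- read_history(store)
  all_rows <- dplyr::bind_rows(old, new_rows)
  readr::write_csv(all_rows, store)
  invisible(history_limits(all_rows, min_history))
}

history_rows <- function(entry, include_below_validity = FALSE) {
  stopifnot(inherits(entry, "worksheet_entry"))
  auto <- entry$automated
  rows <- if (inherits(auto, "mtf_result")) {
    pts <- auto$points
    if (!include_below_validity) pts <- pts[!pts$below_validity, ]
    tibble::tibble(metric = "mtf", object_size_mm = pts$bar_width_mm,
                   value = pts$mtf)
  } else if (is.data.frame(auto)) {
    tibble::as_tibble(auto)
  } else {
    stop("incomplete-entry error: entry has no automated results",
         call. = FALSE)
  }
  dplyr::mutate(rows, device = entry$device, datetime = entry$datetime,
                .before = 1)
}

#' @rdname update_history
#' @export
read_history <- function(store) {
  if (!file.exists(store)) {
    return(tibble::tibble(device = character(), datetime = character(),
                          metric = character(), object_size_mm = numeric(),
                          value = numeric()))
  }
  h <- tryCatch(
    suppressWarnings(readr::read_csv(store, show_col_types = FALSE,
                    col_types = readr::cols(
                      device = readr::col_character(),
                      datetime = readr::col_character(),
                      metric = readr::col_character(),
                      object_size_mm = readr::col_double(),
                      value = readr::col_double()))),
    error = function(e) NULL)
  if (is.null(h) || !all(c("device", "metric", "object_size_mm", "value")
                         %in% names(h))) {
    stop("corrupt history store at ", store, "; move the file aside and ",
         "re-import from your CSV exports, or fix its header to ",
         "device,datetime,metric,object_size_mm,value", call. = FALSE)
  }
  h
}

#' Control-limit summary of a history table
#'
#' @param history Tibble from [read_history()].
#' @param min_history Minimum history per key.
#' @return Tibble of per-(device, metric, object size) limit summaries.
#' @export
history_limits <- function(history, min_history = 10L) {
  history |>
    dplyr::group_by(device, metric, object_size_mm) |>
    dplyr::summarise(limits = list(control_limits(value, min_history)),
                     .groups = "drop") |>
    dplyr::mutate(
      n = purrr::map_int(limits, "n"),
      mu = purrr::map_dbl(limits, "mu"),
      sigma = purrr::map_dbl(limits, "sigma"),
      lower = purrr::map_dbl(limits, "lower"),
      upper = purrr::map_dbl(limits, "upper"),
      range = purrr::map_dbl(limits, "range"),
      status = purrr::map_chr(limits, "status")) |>
    dplyr::select(-limits)
}
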