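#' Circular and line regions of interest
#'
#' ROIs are plain tibbles so ROI sets can be built, filtered and joined with
#' dplyr verbs. A circular ROI has a centre and diameter; a line ROI has two
#' endpoints. All coordinates are physical mm in the image-centred frame.
#'
#' @param x_mm,y_mm Circle centre.
#' @param diameter_mm Circle diameter (> 0).
#' @param label Object name (quadrant, sphere size, sector, position).
#' @return A one-row tibble with class-tagging column `type`.
#' @export
circular_roi <- function(x_mm, y_mm, diameter_mm, label = "") {
  stopifnot(diameter_mm > 0)
  tibble::tibble(label = label, type = "circle", x_mm = x_mm, y_mm = y_mm,
                 diameter_mm = diameter_mm,
                 x0_mm = NA_real_, y0_mm = NA_real_,
                 x1_mm = NA_real_, y1_mm = NA_real_,
                 length_mm = NA_real_)
}

#' @rdname circular_roi
#' @param x0_mm,y0_mm,x1_mm,y1_mm Line endpoints.
#' @export
line_roi <- function(x0_mm, y0_mm, x1_mm, y1_mm, label = "") {
  len <- sqrt((x1_mm - x0_mm)^2 + (y1_mm - y0_mm)^2)
  tibble::tibble(label = label, type = "line", x_mm = NA_real_, y_mm = NA_real_,
                 diameter_mm = NA_real_,
                 x0_mm = x0_mm, y0_mm = y0_mm, x1_mm = x1_mm, y1_mm = y1_mm,
                 length_mm = len)
}

#' Place the four bar-phantom quadrant ROIs
#'
#' One 132-mm circular ROI per quadrant, at the template's (+/-dx, +/-dy)
#' offsets from the detected phantom centre, labelled by the quadrant map's
#' bar-width assignment.
#'
#' @param center A `phantom_center` (or list with `x_mm`, `y_mm`).
#' @param template A [bar_template()].
#' @param image_dim,pixel_spacing_mm Optional image geometry; when supplied,
#'   ROIs extending beyond the image raise a placement error naming the
#'   quadrant.
#' @return Tibble of 4 circular ROIs with a `bar_width_mm` column.
#' @export
place_bar_rois <- function(center, template, image_dim = NULL,
                           pixel_spacing_mm = NULL) {
  stopifnot(inherits(template, "bar_template"))
  qm <- template$quadrant_map
  rois <- purrr::pmap_dfr(qm, function(quadrant, sx, sy, bar_width_mm) {
    dplyr::mutate(
      circular_roi(center$x_mm + sx * template$roi_offset_mm[1],
                   center$y_mm + sy * template$roi_offset_mm[2],
                   template$roi_diameter_mm, label = quadrant),
      bar_width_mm = bar_width_mm)
  })
  check_roi_bounds(rois, image_dim, pixel_spacing_mm)
  rois
}

#' Place ACR-section ROIs
#'
#' * `spheres`: a 69.2-mm background ROI at the phantom centre plus six sphere
#'   ROIs on the sphere ring, the smallest sphere at the 12 o'clock position
#'   and sizes ascending clockwise at 60-degree spacing. Each sphere ROI's
#'   diameter is `sphere_roi_scale` times the physical sphere diameter so
#'   partial-volume losses are measured rather than masked.
#' * `rods`: six 72-mm line ROIs, one per sector, each a chord perpendicular
#'   to the sector bisector, centred on the bisector at the outer rod-row
#'   radius. Sector bisectors start at 12 o'clock (largest rods) and step
#'   -60 degrees.
#' * `uniformity`: a central 50-mm ROI plus four peripheral 50-mm ROIs at
#'   0/90/180/270 degrees on the peripheral radius.
#'
#' @param center A `phantom_center`.
#' @param template An [acr_template()].
#' @param section `"spheres"`, `"rods"` or `"uniformity"`.
#' @inheritParams place_bar_rois
#' @return Tibble of ROIs; sphere/rod rows carry the object size in
#'   `object_size_mm`.
#' @export
place_acr_rois <- function(center, template,
                           section = c("spheres", "rods", "uniformity"),
                           image_dim = NULL, pixel_spacing_mm = NULL) {
  stopifnot(inherits(template, "acr_template"))
  section <- match.arg(section)
  cx <- center$x_mm
  cy <- center$y_mm
  rois <- switch(section,
    spheres = {
      bg <- dplyr::mutate(
        circular_roi(cx, cy, template$background_roi_diameter_mm,
                     label = "background"),
        object_size_mm = NA_real_)
      d_asc <- sort(template$sphere_diameters_mm)   # smallest first
      ring <- template$sphere_ring_radius_mm
      sph <- purrr::imap_dfr(d_asc, function(d, k) {
        ang <- (90 - 60 * (k - 1)) * pi / 180      # smallest at 12 o'clock
        dplyr::mutate(
          circular_roi(cx + ring * cos(ang), cy + ring * sin(ang),
                       template$sphere_roi_scale * d,
                       label = sprintf("sphere_%.1fmm", d)),
          object_size_mm = d)
      })
      dplyr::bind_rows(bg, sph)
    },
    rods = {
      dsc <- template$rod_sector_diameters_mm       # descending
      r_row <- template$rod_row_radius_mm
      half <- template$rod_line_length_mm / 2
      purrr::imap_dfr(dsc, function(d, k) {
        ang <- (90 - 60 * (k - 1)) * pi / 180      # largest sector at 12 o'clock
        u <- c(cos(ang), sin(ang))                 # bisector direction
        v <- c(-sin(ang), cos(ang))                # perpendicular
        mid <- c(cx, cy) + r_row * u
        dplyr::mutate(
          line_roi(mid[1] - half * v[1], mid[2] - half * v[2],
                   mid[1] + half * v[1], mid[2] + half * v[2],
                   label = sprintf("rods_%.1fmm", d)),
          object_size_mm = d)
      })
    },
    uniformity = {
      r <- template$uniformity_peripheral_radius_mm
      d <- template$uniformity_roi_diameter_mm
      pos <- tibble::tibble(
        label = c("center", "east", "north", "west", "south"),
        x = cx + c(0, r, 0, -r, 0), y = cy + c(0, 0, r, 0, -r))
      dplyr::mutate(
        purrr::pmap_dfr(pos, function(label, x, y) circular_roi(x, y, d, label)),
        object_size_mm = NA_real_)
    })
  check_roi_bounds(rois, image_dim, pixel_spacing_mm)
  rois
}

# Error if any ROI leaves the image; no-op when geometry not supplied.
check_roi_bounds <- function(rois, image_dim, pixel_spacing_mm) {
  if (is.null(image_dim) || is.null(pixel_spacing_mm)) return(invisible(rois))
  spacing <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  half_x <- image_dim[2] * spacing[2] / 2
  half_y <- image_dim[1] * spacing[1] / 2
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    out <- if (r$type == "circle") {
      abs(r$x_mm) + r$diameter_mm / 2 > half_x ||
        abs(r$y_mm) + r$diameter_mm / 2 > half_y
    } else {
      max(abs(c(r$x0_mm, r$x1_mm))) > half_x ||
        max(abs(c(r$y0_mm, r$y1_mm))) > half_y
    }
    if (out) stop("placement error: ROI '", r$label,
                  "' extends beyond the image", call. = FALSE)
  }
  invisible(rois)
}

#' ROI pixel statistics
#'
#' Mean, population standard deviation (divide by n) and pixel count over the
#' pixels whose centres fall inside the circle. Pixel-centre membership (no
#' partial-area weighting) keeps the statistic deterministic and fast.
#'
#' @param image Matrix or [planar_image()].
#' @param roi One-row circular ROI tibble (or list with `x_mm`, `y_mm`,
#'   `diameter_mm`).
#' @param pixel_spacing_mm Required for a bare matrix.
#' @param min_pixels Sampling guard: fewer member pixels is an error.
#' @return A list of class `roi_stats` with `mean`, `sd`, `n`.
#' @export
roi_stats <- function(image, roi, pixel_spacing_mm = NULL, min_pixels = 25L) {
  m <- image_matrix(image)
  spacing <- image_spacing(image, pixel_spacing_mm)
  vals <- roi_pixels(m, roi, spacing)
  if (length(vals) < min_pixels) {
    stop("sampling error: ROI '", roi$label %||% "", "' covers only ",
         length(vals), " pixels (minimum ", min_pixels, ")", call. = FALSE)
  }
  mu <- mean(vals)
  list_stats(mu, sqrt(mean((vals - mu)^2)), length(vals))
}

list_stats <- function(mean, sd, n) {
  structure(list(mean = mean, sd = sd, n = n), class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.4g, sd %.4g, n %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

# Values of pixels whose centres lie inside the circular ROI.
roi_pixels <- function(m, roi, spacing) {
  rc <- mm_to_rowcol(roi$x_mm, roi$y_mm, dim(m), spacing)
  rad <- roi$diameter_mm / 2
  rows <- max(1L, floor(rc$row - rad / spacing[1])):
    min(nrow(m), ceiling(rc$row + rad / spacing[1]))
  cols <- max(1L, floor(rc$col - rad / spacing[2])):
    min(ncol(m), ceiling(rc$col + rad / spacing[2]))
  dy <- (rows - rc$row) * spacing[1]
  dx <- (cols - rc$col) * spacing[2]
  inside <- outer(dy^2, dx^2, `+`) < rad^2
  m[rows, cols][inside]
}

#' Sample a line profile by bilinear interpolation
#'
#' Values sampled at uniform steps from the first endpoint towards the second,
#' endpoints inclusive; profile length is `floor(length_mm / step_mm) + 1`.
#'
#' @param image Matrix or [planar_image()].
#' @param roi One-row line ROI tibble.
#' @param step_mm Sampling step in mm (> 0); the rods analysis default is a
#'   quarter pixel.
#' @param pixel_spacing_mm Required for a bare matrix.
#' @return Numeric vector of sampled values.
#' @export
line_profile <- function(image, roi, step_mm, pixel_spacing_mm = NULL) {
  if (step_mm <= 0) stop("parameter error: step_mm must be > 0", call. = FALSE)
  m <- image_matrix(image)
  spacing <- image_spacing(image, pixel_spacing_mm)
  len <- sqrt((roi$x1_mm - roi$x0_mm)^2 + (roi$y1_mm - roi$y0_mm)^2)
  t <- seq(0, by = step_mm, length.out = floor(len / step_mm) + 1) / len
  xs <- roi$x0_mm + t * (roi$x1_mm - roi$x0_mm)
  ys <- roi$y0_mm + t * (roi$y1_mm - roi$y0_mm)
  rc <- mm_to_rowcol(xs, ys, dim(m), spacing)
  bilinear_sample(m, rc$row, rc$col)
}

bilinear_sample <- function(m, row, col) {
  if (any(row < 1 | row > nrow(m) | col < 1 | col > ncol(m))) {
    stop("placement error: line ROI samples outside the image", call. = FALSE)
  }
  r0 <- pmin(floor(row), nrow(m) - 1L)
  c0 <- pmin(floor(col), ncol(m) - 1L)
  fr <- row - r0
  fc <- col - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
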