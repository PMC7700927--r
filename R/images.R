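#' Planar count image with physical geometry
#'
#' Container for a single-frame gamma-camera image: a matrix of counts plus the
#' pixel geometry needed to work in millimetres. The physical frame has its
#' origin at the image centre, x increasing with columns (to the right) and
#' y increasing with decreasing row index (upwards), with the pixel-centre
#' convention for mm/pixel conversion.
#'
#' @param pixels Numeric matrix of counts (non-negative). Must be square:
#'   templates assume square acquisition matrices.
#' @param pixel_spacing_mm Length-2 numeric, (row, col) spacing in mm; a single
#'   value is recycled. Must be positive.
#' @param meta Named list of free-form acquisition metadata (device, datetime,
#'   isotope, collimator, ...).
#' @return An object of class `planar_image`.
#' @seealso [tomo_volume()], [read_planar()]
#' @export
planar_image <- function(pixels, pixel_spacing_mm, meta = list()) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) != ncol(pixels)) {
    stop("geometry error: image matrix must be square (rows == cols), got ",
         nrow(pixels), " x ", ncol(pixels), call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("`pixels` must be non-negative and free of NA", call. = FALSE)
  }
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (anyNA(pixel_spacing_mm) || any(pixel_spacing_mm <= 0)) {
    stop("geometry error: pixel spacing must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         matrix_size = dim(pixels), meta = meta),
    class = "planar_image"
  )
}

#' Reconstructed tomographic volume
#'
#' Ordered stack of transaxial slices with slice geometry. Slices are stored
#' sorted by axial position; all slices must share one matrix size.
#'
#' @param slices List of numeric matrices (one per transaxial slice).
#' @param slice_thickness_mm Positive scalar slice thickness.
#' @param pixel_spacing_mm Length-2 numeric (row, col) spacing in mm.
#' @param slice_positions_mm Numeric vector of axial positions, one per slice.
#'   Slices are re-ordered so positions are increasing.
#' @param meta Named list of acquisition metadata.
#' @return An object of class `tomo_volume`.
#' @export
tomo_volume <- function(slices, slice_thickness_mm, pixel_spacing_mm,
                        slice_positions_mm = NULL, meta = list()) {
  if (!is.list(slices) || length(slices) == 0L) {
    stop("`slices` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("series error: slices have mixed matrix sizes", call. = FALSE)
  }
  slice_thickness_mm <- as.numeric(slice_thickness_mm)
  if (length(slice_thickness_mm) != 1L || is.na(slice_thickness_mm) ||
      slice_thickness_mm <= 0) {
    stop("geometry error: slice thickness must be a positive scalar", call. = FALSE)
  }
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (anyNA(pixel_spacing_mm) || any(pixel_spacing_mm <= 0)) {
    stop("geometry error: pixel spacing must be positive", call. = FALSE)
  }
  if (is.null(slice_positions_mm)) {
    slice_positions_mm <- (seq_along(slices) - 1) * slice_thickness_mm
  }
  if (length(slice_positions_mm) != length(slices)) {
    stop("series error: one position per slice required", call. = FALSE)
  }
  ord <- order(slice_positions_mm)
  structure(
    list(slices = slices[ord], slice_thickness_mm = slice_thickness_mm,
         pixel_spacing_mm = pixel_spacing_mm,
         slice_positions_mm = as.numeric(slice_positions_mm[ord]),
         meta = meta),
    class = "tomo_volume"
  )
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d, %.4g x %.4g mm/px, total counts %.6g\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], sum(x$pixels)))
  invisible(x)
}

#' @export
print.tomo_volume <- function(x, ...) {
  cat(sprintf("<tomo_volume> %d slices of %d x %d, %.4g mm/px, thickness %.4g mm\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$pixel_spacing_mm[1], x$slice_thickness_mm))
  invisible(x)
}

# mm <-> pixel conversion (pixel-centre convention, origin at image centre,
# y up).  `row`/`col` are 1-based fractional indices.
mm_to_rowcol <- function(x_mm, y_mm, dim, spacing) {
  list(row = (dim[1] + 1) / 2 - y_mm / spacing[1],
       col = x_mm / spacing[2] + (dim[2] + 1) / 2)
}

rowcol_to_mm <- function(row, col, dim, spacing) {
  list(x_mm = (col - (dim[2] + 1) / 2) * spacing[2],
       y_mm = ((dim[1] + 1) / 2 - row) * spacing[1])
}

# Pull the pixel matrix out of a planar_image, tomo slice or bare matrix.
image_matrix <- function(image) {
  if (inherits(image, "planar_image")) return(image$pixels)
  if (is.matrix(image)) return(image)
  stop("expected a planar_image or matrix", call. = FALSE)
}

image_spacing <- function(image, pixel_spacing_mm = NULL) {
  if (inherits(image, "planar_image")) return(image$pixel_spacing_mm)
  if (is.null(pixel_spacing_mm)) {
    stop("geometry error: pixel spacing required for a bare matrix", call. = FALSE)
  }
  rep_len(as.numeric(pixel_spacing_mm), 2L)
}

#' Extract one slice of a volume as a planar frame
#'
#' @param volume A [tomo_volume()].
#' @param slice Slice index (1-based).
#' @return A list with `pixels`, `pixel_spacing_mm` and `position_mm`.
#' @export
volume_slice <- function(volume, slice) {
  stopifnot(inherits(volume, "tomo_volume"))
  if (slice < 1 || slice > length(volume$slices)) {
    stop("slice index ", slice, " out of range 1..", length(volume$slices),
         call. = FALSE)
  }
  list(pixels = volume$slices[[slice]],
       pixel_spacing_mm = volume$pixel_spacing_mm,
       position_mm = volume$slice_positions_mm[slice])
}
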