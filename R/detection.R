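#' Preprocess a phantom image for detection
#'
#' Grayscale morphological dilation followed by erosion (a closing, which
#' removes small dark objects such as the lead bars) and an optional Gaussian
#' blur. Used only to build the detection mask; metric extraction always runs
#' on the raw counts.
#'
#' @param image A [planar_image()], a volume slice, or a bare matrix.
#' @param kernel_px Side of the square structuring element in pixels (odd).
#' @param blur_sigma_px Gaussian blur sigma in pixels; `0` disables the blur
#'   (the ACR slice preprocessing uses closing only).
#' @return Matrix of the same shape, values >= 0.
#' @export
preprocess_phantom <- function(image, kernel_px = 3L, blur_sigma_px = 1) {
  m <- image_matrix(image)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L || kernel_px > min(dim(m))) {
    stop("parameter error: kernel size ", kernel_px,
         " invalid for a ", nrow(m), " x ", ncol(m), " image", call. = FALSE)
  }
  out <- m
  if (kernel_px > 1L) {
    out <- minmax_filter(minmax_filter(out, kernel_px, pmax), kernel_px, pmin)
  }
  if (blur_sigma_px > 0) {
    out <- EBImage::gblur(out, sigma = blur_sigma_px)
  }
  out[out < 0] <- 0
  out
}


# separable grayscale running max/min over a k x k box (dilation/erosion with
# a square structuring element), with edge replication
minmax_filter <- function(m, k, op) {
  r <- (k - 1L) %/% 2L
  run1 <- function(x) {
    out <- x
    for (d in seq_len(r)) {
      n <- length(x)
      out <- op(out, c(x[-seq_len(d)], rep(x[n], d)),
                c(rep(x[1], d), x[seq_len(n - d)]))
    }
    out
  }
  m <- apply(m, 2L, run1)
  t(apply(m, 1L, run1))
}

#' Detect the phantom and locate its centre
#'
#' Thresholds the (preprocessed) image at a configurable fraction of its
#' 99.5th-percentile intensity, labels connected components, and returns the
#' binary-mask centroid of the largest component in physical mm. A mask (not
#' intensity) centroid is used so that quadrants with different mean counts do
#' not bias the centre.
#'
#' @param image Preprocessed matrix or [planar_image()].
#' @param pixel_spacing_mm Required when `image` is a bare matrix.
#' @param threshold_fraction Relative threshold (fraction of the 99.5th
#'   percentile); default 0.10. Using a relative threshold makes detection
#'   invariant to global count scaling.
#' @param min_area_mm2 Smallest acceptable mask area; below it detection fails.
#' @return A list of class `phantom_center` with `x_mm`, `y_mm`,
#'   `mask_area_mm2` and the binary `mask`.
#' @export
detect_center <- function(image, pixel_spacing_mm = NULL,
                          threshold_fraction = 0.10, min_area_mm2 = 2000) {
  m <- image_matrix(image)
  spacing <- image_spacing(image, pixel_spacing_mm)
  px_area <- prod(spacing)
  if (all(m <= 0)) stop("detection error: phantom not found (empty image)",
                        call. = FALSE)
  thr <- threshold_fraction * stats::quantile(m, 0.995, names = FALSE)
  mask <- m > thr
  labels <- EBImage::bwlabel(mask)
  n_comp <- max(labels)
  if (n_comp == 0) stop("detection error: phantom not found", call. = FALSE)
  areas <- tabulate(labels[labels > 0], nbins = n_comp)
  # deterministic tie-break: larger area, then smaller centroid row index
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    rows <- vapply(best, function(k) {
      mean(which(labels == k, arr.ind = TRUE)[, 1])
    }, numeric(1))
    best <- best[which.min(rows)]
  }
  if (n_comp > 1L && sum(areas[-best[1]] >= 0.5 * areas[best[1]]) > 0) {
    warning("ambiguous detection: multiple similar-size components; ",
            "largest chosen", call. = FALSE)
  }
  best <- best[1]
  area_mm2 <- areas[best] * px_area
  if (area_mm2 < min_area_mm2) {
    stop("detection error: phantom not found (largest component ",
         round(area_mm2), " mm^2 below minimum ", min_area_mm2, " mm^2)",
         call. = FALSE)
  }
  idx <- which(labels == best, arr.ind = TRUE)
  ctr <- rowcol_to_mm(mean(idx[, 1]), mean(idx[, 2]), dim(m), spacing)
  structure(list(x_mm = ctr$x_mm, y_mm = ctr$y_mm,
                 mask_area_mm2 = area_mm2, mask = labels == best),
            class = "phantom_center")
}

#' @export
print.phantom_center <- function(x, ...) {
  cat(sprintf("<phantom_center> (%.2f, %.2f) mm, mask area %.0f mm^2\n",
              x$x_mm, x$y_mm, x$mask_area_mm2))
  invisible(x)
}

# Full detection step used by the analyze_* drivers: preprocess then locate.
detect_phantom <- function(image, pixel_spacing_mm = NULL, params = NULL,
                           blur = TRUE) {
  p <- detection_params(params)
  pre <- preprocess_phantom(image, kernel_px = p$kernel_px,
                            blur_sigma_px = if (blur) p$blur_sigma_px else 0)
  detect_center(pre, pixel_spacing_mm = image_spacing(image, pixel_spacing_mm),
                threshold_fraction = p$threshold_fraction,
                min_area_mm2 = p$min_area_mm2)
}
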