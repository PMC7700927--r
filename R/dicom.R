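# Minimal DICOM codec for uncompressed phantom images.
#
# Writes Explicit VR Little Endian single-frame (or multi-frame) monochrome
# images with a standard 128-byte preamble and file-meta group; reads both
# Explicit and Implicit VR Little Endian with defined element lengths.
# Compressed transfer syntaxes, sequences and big-endian files are out of
# scope: phantom QC exports are plain reconstructed/static frames.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_NM <- "1.2.840.10008.5.1.4.1.1.20"
UID_ROOT <- "1.2.826.0.1.3680043.10.424"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16_raw <- function(v) {
  v <- as.integer(v)
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2, endian = "little")
}

uint32_raw <- function(v) writeBin(as.integer(v), raw(), size = 4,
                                   endian = "little")

str_value <- function(x, pad_nul = FALSE) {
  b <- charToRaw(as.character(x))
  if (length(b) %% 2 == 1) b <- c(b, if (pad_nul) as.raw(0) else charToRaw(" "))
  b
}

dcm_element <- function(group, elem, vr, value) {
  stopifnot(length(value) %% 2 == 0)
  header <- c(uint16_raw(group), uint16_raw(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(header, as.raw(c(0, 0)), uint32_raw(length(value)), value)
  } else {
    c(header, uint16_raw(length(value)), value)
  }
}

# monotone UID generator; deliberately avoids the RNG so that writing files
# never perturbs seeded simulation streams
.uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

new_uid <- function() {
  paste0(UID_ROOT, ".", format(as.integer(Sys.time()) %% 1e9L), ".",
         Sys.getpid() %% 1e5L, ".", .uid_counter())
}

dcm_meta_group <- function(sop_instance_uid) {
  body <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dcm_element(2L, 2L, "UI", str_value(SOP_NM, pad_nul = TRUE)),
    dcm_element(2L, 3L, "UI", str_value(sop_instance_uid, pad_nul = TRUE)),
    dcm_element(2L, 16L, "UI", str_value(TS_EXPLICIT_LE, pad_nul = TRUE)),
    dcm_element(2L, 18L, "UI", str_value(paste0(UID_ROOT, ".1"), pad_nul = TRUE)))
  c(as.raw(rep(0, 128)), charToRaw("DICM"),
    dcm_element(2L, 0L, "UL", uint32_raw(length(body))), body)
}

# choose integer storage: slope 1 for integral data within 16 bits, else a
# scale factor (read applies slope * stored + intercept)
pixel_encoding <- function(values) {
  mx <- max(values)
  if (mx <= 65535 && all(values == round(values))) {
    list(slope = 1, intercept = 0, stored = as.integer(round(values)))
  } else {
    slope <- if (mx > 0) mx / 65535 else 1
    list(slope = slope, intercept = 0,
         stored = as.integer(round(values / slope)))
  }
}

dcm_dataset <- function(frames, spacing, meta, slice_thickness = NULL,
                        slice_location = NULL, spacing_between = NULL,
                        instance_number = 1L) {
  rows <- nrow(frames[[1]])
  cols <- ncol(frames[[1]])
  # pixel data row-major, frames concatenated
  values <- unlist(lapply(frames, function(f) as.vector(t(f))))
  enc <- pixel_encoding(values)
  pix <- uint16_raw(enc$stored)
  ds <- c(
    dcm_element(8L, 0x16L, "UI", str_value(SOP_NM, pad_nul = TRUE)),
    dcm_element(8L, 0x18L, "UI", str_value(new_uid(), pad_nul = TRUE)),
    dcm_element(8L, 0x20L, "DA", str_value(meta[["date"]] %||% "20260101")),
    dcm_element(8L, 0x30L, "TM", str_value(meta[["time"]] %||% "000000")),
    dcm_element(8L, 0x60L, "CS", str_value("NM")),
    dcm_element(8L, 0x1010L, "SH", str_value(meta[["device"]] %||% "UNKNOWN")),
    dcm_element(8L, 0x103EL, "LO", str_value(meta[["phantom"]] %||% "phantom")),
    dcm_element(0x10L, 0x10L, "PN", str_value("PHANTOM^QC")),
    dcm_element(0x10L, 0x20L, "LO", str_value("QC")),
    dcm_element(0x18L, 0x31L, "LO", str_value(meta[["isotope"]] %||% "")),
    if (!is.null(slice_thickness))
      dcm_element(0x18L, 0x50L, "DS", str_value(format(slice_thickness))),
    if (!is.null(spacing_between))
      dcm_element(0x18L, 0x88L, "DS", str_value(format(spacing_between))),
    dcm_element(0x18L, 0x1181L, "CS", str_value(meta[["collimator"]] %||% "")),
    dcm_element(0x20L, 0x0DL, "UI",
                str_value(meta[["study_uid"]] %||% new_uid(), pad_nul = TRUE)),
    dcm_element(0x20L, 0x0EL, "UI",
                str_value(meta[["series_uid"]] %||% new_uid(), pad_nul = TRUE)),
    dcm_element(0x20L, 0x13L, "IS", str_value(instance_number)),
    if (!is.null(slice_location))
      dcm_element(0x20L, 0x1041L, "DS", str_value(format(slice_location))),
    dcm_element(0x28L, 0x02L, "US", uint16_raw(1L)),
    dcm_element(0x28L, 0x04L, "CS", str_value("MONOCHROME2")),
    if (length(frames) > 1L)
      dcm_element(0x28L, 0x08L, "IS", str_value(length(frames))),
    dcm_element(0x28L, 0x10L, "US", uint16_raw(rows)),
    dcm_element(0x28L, 0x11L, "US", uint16_raw(cols)),
    dcm_element(0x28L, 0x30L, "DS",
                str_value(paste0(format(spacing[1]), "\\", format(spacing[2])))),
    dcm_element(0x28L, 0x100L, "US", uint16_raw(16L)),
    dcm_element(0x28L, 0x101L, "US", uint16_raw(16L)),
    dcm_element(0x28L, 0x102L, "US", uint16_raw(15L)),
    dcm_element(0x28L, 0x103L, "US", uint16_raw(0L)),
    dcm_element(0x28L, 0x1052L, "DS",
                str_value(format(enc$intercept, digits = 10))),
    dcm_element(0x28L, 0x1053L, "DS",
                str_value(format(enc$slope, digits = 10))),
    dcm_element(0x7FE0L, 0x10L, "OW", pix))
  ds
}

#' Write images as DICOM files
#'
#' Writes standards-conformant uncompressed Explicit VR Little Endian files.
#' Integer count images round-trip bit-identically; non-integral or
#' out-of-range data are stored via a rescale slope (lossy at the 16-bit
#' quantisation level).
#'
#' @param x A [planar_image()] or [tomo_volume()].
#' @param path Output file (planar) or directory (volume).
#' @param ... Passed to methods.
#' @return Invisibly, the written file path(s).
#' @export
write_dicom <- function(x, path, ...) UseMethod("write_dicom")

#' @export
write_dicom.planar_image <- function(x, path, ...) {
  body <- dcm_dataset(list(x$pixels), x$pixel_spacing_mm, x$meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(dcm_meta_group(new_uid()), body), con)
  invisible(path)
}

#' @rdname write_dicom
#' @param multiframe Write the volume as one multi-frame file instead of one
#'   file per slice.
#' @export
write_dicom.tomo_volume <- function(x, path, multiframe = FALSE, ...) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- x$meta
  meta$study_uid <- meta[["study_uid"]] %||% new_uid()
  meta$series_uid <- meta[["series_uid"]] %||% new_uid()
  if (multiframe) {
    f <- file.path(path, "volume.dcm")
    body <- dcm_dataset(x$slices, x$pixel_spacing_mm, meta,
                        slice_thickness = x$slice_thickness_mm,
                        slice_location = x$slice_positions_mm[1],
                        spacing_between = x$slice_thickness_mm)
    con <- file(f, "wb")
    writeBin(c(dcm_meta_group(new_uid()), body), con)
    close(con)
    return(invisible(f))
  }
  paths <- character(length(x$slices))
  for (i in seq_along(x$slices)) {
    f <- file.path(path, sprintf("slice_%03d.dcm", i))
    body <- dcm_dataset(x$slices[i], x$pixel_spacing_mm, meta,
                        slice_thickness = x$slice_thickness_mm,
                        slice_location = x$slice_positions_mm[i],
                        instance_number = i)
    con <- file(f, "wb")
    writeBin(c(dcm_meta_group(new_uid()), body), con)
    close(con)
    paths[i] <- f
  }
  invisible(paths)
}

# ---- reading ---------------------------------------------------------------

parse_dicom <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  pos <- 1L
  explicit <- TRUE
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
    # file meta group is always explicit; transfer syntax decides the rest
  } else if (length(bytes) < 8) {
    stop("format error: not a DICOM file: ", path, call. = FALSE)
  }
  elements <- new.env(parent = emptyenv())
  ts <- TS_EXPLICIT_LE
  in_meta <- pos > 1L
  repeat {
    if (pos + 7L > length(bytes)) break
    group <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2,
                     endian = "little", signed = FALSE)
    elem <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2,
                    endian = "little", signed = FALSE)
    pos <- pos + 4L
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- !identical(ts, TS_IMPLICIT_LE)
      if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
        stop("format error: unsupported transfer syntax ", ts, call. = FALSE)
      }
    }
    use_explicit <- explicit || in_meta || group == 2L
    if (use_explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      pos <- pos + 2L
      if (vr %in% LONG_VRS) {
        len <- readBin(bytes[(pos + 2L):(pos + 5L)], "integer", size = 4,
                       endian = "little")
        pos <- pos + 6L
      } else {
        len <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2,
                       endian = "little", signed = FALSE)
        pos <- pos + 2L
      }
    } else {
      vr <- NA_character_
      len <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 4L
    }
    if (is.na(len) || len < 0) {
      stop("format error: undefined element lengths are not supported",
           call. = FALSE)
    }
    key <- sprintf("%04X,%04X", group, elem)
    elements[[key]] <- bytes[seq.int(pos, length.out = len)]
    pos <- pos + len
    if (in_meta && group == 2L && elem == 16L) {
      v <- elements[[key]]
      ts <- trimws(rawToChar(v[v != as.raw(0)]))
    }
  }
  elements
}

el_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0)]))
}

el_ds <- function(el, key) {
  s <- el_str(el, key)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

el_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  readBin(v, "integer", n = length(v) / 2, size = 2, endian = "little",
          signed = FALSE)
}

dicom_frames <- function(el, path) {
  pix_raw <- el[["7FE0,0010"]]
  if (is.null(pix_raw)) {
    stop("format error: no pixel data in ", path, call. = FALSE)
  }
  rows <- el_us(el, "0028,0010")
  cols <- el_us(el, "0028,0011")
  if (is.null(rows) || is.null(cols)) {
    stop("format error: missing Rows/Columns in ", path, call. = FALSE)
  }
  bits <- el_us(el, "0028,0100") %||% 16L
  if (bits != 16L) {
    stop("format error: only 16-bit pixel data supported", call. = FALSE)
  }
  spacing <- el_ds(el, "0028,0030")
  if (is.null(spacing)) {
    stop("geometry error: pixel spacing missing from the header of ", path,
         " (no default is assumed)", call. = FALSE)
  }
  slope <- (el_ds(el, "0028,1053") %||% 1)[1]
  intercept <- (el_ds(el, "0028,1052") %||% 0)[1]
  stored <- readBin(pix_raw, "integer", n = length(pix_raw) / 2, size = 2,
                    endian = "little", signed = FALSE)
  nframes <- as.integer(el_str(el, "0028,0008") %||% "1")
  per_frame <- rows * cols
  if (length(stored) != per_frame * nframes) {
    stop("format error: pixel data size does not match Rows x Columns",
         call. = FALSE)
  }
  frames <- lapply(seq_len(nframes), function(k) {
    v <- stored[((k - 1) * per_frame + 1):(k * per_frame)] * slope + intercept
    matrix(v, rows, cols, byrow = TRUE)
  })
  list(frames = frames, spacing = rep_len(spacing, 2L),
       thickness = (el_ds(el, "0018,0050") %||% NA_real_)[1],
       spacing_between = (el_ds(el, "0018,0088") %||% NA_real_)[1],
       location = (el_ds(el, "0020,1041") %||% NA_real_)[1],
       meta = list(device = el_str(el, "0008,1010"),
                   datetime = paste0(el_str(el, "0008,0020") %||% "",
                                     "T", el_str(el, "0008,0030") %||% ""),
                   isotope = el_str(el, "0018,0031"),
                   collimator = el_str(el, "0018,1181"),
                   phantom = el_str(el, "0008,103E")))
}

#' Read a single-frame planar DICOM image
#'
#' Applies the rescale slope/intercept on read so pixel values are in stored
#' count units; pixel spacing must be present in the header (no silent 1-mm
#' default) and the matrix must be square.
#'
#' @param path Path to a DICOM file.
#' @return A [planar_image()].
#' @export
read_planar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- dicom_frames(parse_dicom(path), path)
  if (length(d$frames) != 1L) {
    stop("format error: expected a single-frame planar image", call. = FALSE)
  }
  m <- d$frames[[1]]
  if (nrow(m) != ncol(m)) {
    stop("geometry error: non-square matrix (", nrow(m), " x ", ncol(m), ")",
         call. = FALSE)
  }
  planar_image(m, d$spacing, meta = d$meta)
}

#' Read a reconstructed DICOM series as a volume
#'
#' Accepts a directory, a vector of single-frame files, or one multi-frame
#' file. Slices are sorted by axial position; the slice thickness is taken
#' from the header or inferred from the inter-slice distance. Mixed matrix
#' sizes or pixel spacings, and position gaps beyond 25% of the median
#' spacing, are series errors.
#'
#' @param paths Directory or character vector of DICOM file paths.
#' @return A [tomo_volume()].
#' @export
read_volume <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.dcm$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("series error: no DICOM files", call. = FALSE)
  parts <- lapply(paths, function(p) dicom_frames(parse_dicom(p), p))
  dims <- vapply(parts, function(p) dim(p$frames[[1]]), integer(2))
  if (any(dims != dims[, 1])) {
    stop("series error: slices have mixed matrix sizes", call. = FALSE)
  }
  spac <- vapply(parts, function(p) p$spacing, numeric(2))
  if (any(abs(spac - spac[, 1]) > 1e-6)) {
    stop("series error: slices have mixed pixel spacings", call. = FALSE)
  }
  if (length(parts) == 1L && length(parts[[1]]$frames) > 1L) {
    p <- parts[[1]]
    step <- if (is.finite(p$spacing_between)) p$spacing_between else
      if (is.finite(p$thickness)) p$thickness else
        stop("series error: multi-frame file lacks slice spacing",
             call. = FALSE)
    loc0 <- if (is.finite(p$location)) p$location else 0
    positions <- loc0 + (seq_along(p$frames) - 1) * step
    return(tomo_volume(p$frames, step, p$spacing, positions, meta = p$meta))
  }
  frames <- lapply(parts, function(p) {
    if (length(p$frames) != 1L) {
      stop("series error: mixed single- and multi-frame files", call. = FALSE)
    }
    p$frames[[1]]
  })
  positions <- vapply(parts, function(p) p$location, numeric(1))
  if (anyNA(positions)) {
    stop("series error: slice location missing from one or more files",
         call. = FALSE)
  }
  ord <- order(positions)
  steps <- diff(positions[ord])
  med <- stats::median(steps)
  if (length(steps) && (med <= 0 || any(abs(steps - med) > 0.25 * med))) {
    stop("series error: inconsistent or gapped slice positions", call. = FALSE)
  }
  thick <- vapply(parts, function(p) p$thickness, numeric(1))
  thickness <- if (all(is.finite(thick))) thick[1] else med
  tomo_volume(frames, thickness, parts[[1]]$spacing, positions,
              meta = parts[[1]]$meta)
}
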