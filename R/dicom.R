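# Minimal single-frame DICOM support (Explicit VR Little Endian only).
# Covers exactly what a reconstructed CT series needs: pixel geometry,
# rescale, series identity and ordering tags. Sequences, compressed transfer
# syntaxes and multi-frame objects are out of scope.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

#' Read a single-frame DICOM series into a grey-value volume
#'
#' Reads every parsable DICOM file in `directory`, checks that all files
#' belong to one series with consistent in-plane dimensions, sorts slices by
#' image position (fallbacks: slice location, then instance number), applies
#' each file's rescale slope/intercept and casts to signed 16-bit (values
#' outside the int16 range are clamped with a warning). Voxel spacing is
#' taken from the pixel-spacing tag; slice spacing from the
#' spacing-between-slices tag, falling back to inter-slice position
#' differences and finally to 0.5 mm with a warning.
#'
#' Only uncompressed Explicit VR Little Endian, single-frame files are
#' supported.
#'
#' @param directory path containing the DICOM files (any file names).
#' @return A [grey_volume()] with axis order (slice, row, col).
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) abort("no DICOM found: directory does not exist")
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- list()
  for (f in files) {
    p <- tryCatch(parse_dicom_file(f), error = function(e) NULL)
    if (!is.null(p)) parsed[[length(parsed) + 1L]] <- p
  }
  if (length(parsed) == 0L) abort("no DICOM found")

  uids <- vapply(parsed, function(p) p$series_uid %||% "", "")
  if (length(unique(uids)) != 1L) {
    abort("inconsistent series: multiple series UIDs")
  }
  dims <- vapply(parsed, function(p) c(p$rows, p$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("inconsistent series: row/col dimensions differ")
  }

  pos <- vapply(parsed, function(p) {
    if (!is.null(p$image_position)) p$image_position[3]
    else if (!is.null(p$slice_location)) p$slice_location
    else NA_real_
  }, 0)
  ord <- if (all(is.finite(pos))) {
    order(pos)
  } else {
    order(vapply(parsed, function(p) p$instance_number %||% NA_integer_,
                 0L))
  }
  parsed <- parsed[ord]
  pos <- pos[ord]

  nr <- parsed[[1]]$rows
  nc <- parsed[[1]]$cols
  ns <- length(parsed)
  vox <- array(0L, c(ns, nr, nc))
  clamped <- FALSE
  for (s in seq_len(ns)) {
    p <- parsed[[s]]
    v <- p$pixels * (p$rescale_slope %||% 1) + (p$rescale_intercept %||% 0)
    if (any(v < -32768 | v > 32767)) {
      clamped <- TRUE
      v[v < -32768] <- -32768
      v[v > 32767] <- 32767
    }
    vox[s, , ] <- matrix(as.integer(round(v)), nr, nc, byrow = TRUE)
  }
  if (clamped) warn("rescaled values outside int16 were clamped")

  ps <- parsed[[1]]$pixel_spacing %||% c(1, 1)
  slice_sp <- parsed[[1]]$spacing_between_slices
  if (is.null(slice_sp)) {
    dpos <- diff(pos)
    if (length(dpos) >= 1L && all(is.finite(dpos)) &&
        all(abs(dpos - dpos[1]) < 1e-6) && dpos[1] > 0) {
      slice_sp <- dpos[1]
    } else {
      warn("no slice-spacing tag or usable positions; assuming 0.5 mm")
      slice_sp <- 0.5
    }
  }
  grey_volume(
    vox,
    spacing_mm = c(slice_sp, ps[1], ps[2]),
    series_meta = list(
      series_uid = parsed[[1]]$series_uid,
      n_files = ns,
      rescale_slope = parsed[[1]]$rescale_slope %||% 1,
      rescale_intercept = parsed[[1]]$rescale_intercept %||% 0
    )
  )
}

# ---- low-level parsing -----------------------------------------------------

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 132L ||
      rawToChar(raw[129:132]) != "DICM") {
    abort("not DICOM")
  }
  elems <- parse_dicom_elements(raw, 133L)
  ts <- elems[["0002,0010"]]
  if (!is.null(ts) && trimws(ts) != EXPLICIT_VR_LE) {
    abort("unsupported transfer syntax")
  }
  rows <- as.integer(elems[["0028,0010"]])
  cols <- as.integer(elems[["0028,0011"]])
  bits <- as.integer(elems[["0028,0100"]] %||% 16L)
  signed <- as.integer(elems[["0028,0103"]] %||% 1L) == 1L
  pix_raw <- elems[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix_raw)) {
    abort("missing required tags")
  }
  if (bits != 16L) abort("only 16-bit pixel data supported")
  pixels <- readBin(pix_raw, "integer", n = length(pix_raw) / 2L,
                    size = 2L, signed = signed, endian = "little")
  if (length(pixels) != rows * cols) abort("pixel data length mismatch")
  list(
    series_uid = str_or_null(elems[["0020,000e"]]),
    instance_number = num_or_null(elems[["0020,0013"]]),
    image_position = nums_or_null(elems[["0020,0032"]]),
    slice_location = num_or_null(elems[["0020,1041"]]),
    pixel_spacing = nums_or_null(elems[["0028,0030"]]),
    slice_thickness = num_or_null(elems[["0018,0050"]]),
    spacing_between_slices = num_or_null(elems[["0018,0088"]]),
    rescale_intercept = num_or_null(elems[["0028,1052"]]),
    rescale_slope = num_or_null(elems[["0028,1053"]]),
    rows = rows, cols = cols, pixels = pixels
  )
}

str_or_null <- function(x) if (is.null(x)) NULL else trimws(x)
num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(trimws(x))
nums_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  as.numeric(strsplit(trimws(x), "\\\\")[[1]])
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UI", "UT")

parse_dicom_elements <- function(raw, offset) {
  out <- list()
  n <- length(raw)
  i <- offset
  u16 <- function(at) {
    as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  }
  u32 <- function(at) {
    as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
      65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  }
  while (i + 7L <= n) {
    group <- u16(i)
    elem <- u16(i + 2L)
    vr <- rawToChar(raw[(i + 4L):(i + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(i + 8L)
      val_at <- i + 12L
    } else {
      len <- u16(i + 6L)
      val_at <- i + 8L
    }
    if (len == 4294967295 || vr == "SQ") {
      abort("unsupported DICOM encoding (undefined length / sequence)")
    }
    if (val_at + len - 1L > n) abort("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, elem)
    if (len > 0L) {
      val <- raw[val_at:(val_at + len - 1L)]
      out[[key]] <- if (vr %in% c("OB", "OW")) {
        val
      } else if (vr == "US") {
        u16(val_at)
      } else if (vr == "UL") {
        u32(val_at)
      } else if (vr %in% STRING_VRS) {
        rawToChar(val[val != as.raw(0)])
      } else {
        val
      }
    }
    i <- val_at + len
  }
  out
}

# ---- writing (synthetic fixture support) -----------------------------------

#' Write a grey volume as a minimal synthetic DICOM series
#'
#' Writes one uncompressed Explicit VR Little Endian, single-frame DICOM
#' file per slice. This writer exists to produce *synthetic* fixtures for
#' exercising [read_dicom_series()] and downstream code; it emits only the
#' geometry, ordering and rescale tags that the reader consumes and is not a
#' conformant clinical DICOM implementation.
#'
#' Stored pixel values are `(grey - rescale_intercept) / rescale_slope`,
#' so reading the series back recovers the original grey values.
#'
#' @param volume a [grey_volume()].
#' @param directory output directory (created if missing).
#' @param rescale_slope,rescale_intercept rescale header values to embed.
#' @param file_names optional character vector of file names (default
#'   `slice_###.dcm`), useful for testing order independence.
#' @param series_uid series UID string; a fixed synthetic default.
#' @return The directory path, invisibly.
#' @export
write_synthetic_dicom_series <- function(volume, directory,
                                         rescale_slope = 1,
                                         rescale_intercept = 0,
                                         file_names = NULL,
                                         series_uid = "1.2.826.0.1.3680043.9.7433.1") {
  stopifnot(inherits(volume, "grey_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  if (is.null(file_names)) {
    file_names <- sprintf("slice_%03d.dcm", seq_len(d[1]))
  }
  stopifnot(length(file_names) == d[1])
  for (s in seq_len(d[1])) {
    stored <- (volume$voxels[s, , ] - rescale_intercept) / rescale_slope
    stored <- as.integer(round(stored))
    if (any(stored < -32768 | stored > 32767)) {
      abort("stored pixel values exceed int16 under the given rescale")
    }
    write_dicom_slice(
      file.path(directory, file_names[s]),
      pixels = stored, nrow = d[2], ncol = d[3],
      slice_index = s, spacing = volume$spacing_mm,
      rescale_slope = rescale_slope,
      rescale_intercept = rescale_intercept,
      series_uid = series_uid
    )
  }
  invisible(directory)
}

write_dicom_slice <- function(path, pixels, nrow, ncol, slice_index, spacing,
                              rescale_slope, rescale_intercept, series_uid) {
  enc_short <- function(group, elem, vr, val_raw) {
    if (length(val_raw) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      val_raw <- c(val_raw, pad)
    }
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr),
      writeBin(length(val_raw), raw(), size = 2, endian = "little"),
      val_raw)
  }
  enc_long <- function(group, elem, vr, val_raw) {
    if (length(val_raw) %% 2L == 1L) val_raw <- c(val_raw, as.raw(0))
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(val_raw), raw(), size = 4, endian = "little"),
      val_raw)
  }
  str_el <- function(group, elem, vr, s) {
    enc_short(group, elem, vr, charToRaw(s))
  }
  us_el <- function(group, elem, v) {
    enc_short(group, elem, "US", writeBin(as.integer(v), raw(), size = 2,
                                          endian = "little"))
  }
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                          collapse = "\\")

  meta <- c(
    str_el(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    str_el(0x0002L, 0x0003L, "UI", paste0(series_uid, ".", slice_index)),
    str_el(0x0002L, 0x0010L, "UI", EXPLICIT_VR_LE)
  )
  group_len <- enc_short(0x0002L, 0x0000L, "UL",
                         writeBin(length(meta), raw(), size = 4,
                                  endian = "little"))

  # pixels arrive as a (row, col) matrix; DICOM stores row-major
  px_vals <- as.integer(as.vector(t(matrix(pixels, nrow, ncol))))
  px <- writeBin(px_vals, raw(), size = 2, endian = "little")
  body <- c(
    str_el(0x0008L, 0x0016L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    str_el(0x0008L, 0x0018L, "UI", paste0(series_uid, ".", slice_index)),
    str_el(0x0018L, 0x0050L, "DS", ds(spacing[1])),
    str_el(0x0018L, 0x0088L, "DS", ds(spacing[1])),
    str_el(0x0020L, 0x000eL, "UI", series_uid),
    str_el(0x0020L, 0x0013L, "IS", as.character(slice_index)),
    str_el(0x0020L, 0x0032L, "DS",
           ds(c(0, 0, (slice_index - 0.5) * spacing[1]))),
    str_el(0x0020L, 0x1041L, "DS", ds((slice_index - 0.5) * spacing[1])),
    us_el(0x0028L, 0x0002L, 1L),
    us_el(0x0028L, 0x0010L, nrow),
    us_el(0x0028L, 0x0011L, ncol),
    str_el(0x0028L, 0x0030L, "DS", ds(c(spacing[2], spacing[3]))),
    us_el(0x0028L, 0x0100L, 16L),
    us_el(0x0028L, 0x0101L, 16L),
    us_el(0x0028L, 0x0102L, 15L),
    us_el(0x0028L, 0x0103L, 1L),
    str_el(0x0028L, 0x1052L, "DS", ds(rescale_intercept)),
    str_el(0x0028L, 0x1053L, "DS", ds(rescale_slope)),
    enc_long(0x7fe0L, 0x0010L, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}
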