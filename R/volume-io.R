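#' Write a volume to disk (TIFF stack or CSV slices)
#'
#' `format = "tiff_stack"` writes one multi-page TIFF (one page per slice);
#' `format = "csv_slices"` writes one CSV per slice. Either way a JSON
#' sidecar (`<path>.json`) records the spacing, the value kind and the
#' scaling needed to restore physical values, so [read_volume()] can
#' round-trip the result. Integer grey volumes round-trip bit-exactly
#' (stored as 16-bit samples); porosity volumes are stored as 32-bit floats
#' and round-trip to single precision.
#'
#' @param volume a [grey_volume()] or [porosity_volume()].
#' @param path output path: the TIFF file for `tiff_stack`, or a directory
#'   for `csv_slices`.
#' @param format `"tiff_stack"` or `"csv_slices"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("tiff_stack", "csv_slices")) {
  if (!is.character(format) || !all(format %in% c("tiff_stack", "csv_slices"))) {
    abort("unknown format")
  }
  format <- match.arg(format)
  is_grey <- inherits(volume, "grey_volume")
  if (!is_grey && !inherits(volume, "porosity_volume")) {
    abort("`volume` must be a grey_volume or porosity_volume")
  }
  arr <- vol_array(volume)
  d <- dim(arr)
  if (is_grey) {
    lo <- -32768; hi <- 32767
    scaled <- (arr - lo) / (hi - lo)
    bits <- 16L
  } else {
    lo <- min(arr); hi <- max(arr)
    scaled <- if (hi > lo) (arr - lo) / (hi - lo) else array(0, d)
    bits <- 32L
  }
  sidecar <- list(
    kind = if (is_grey) "grey" else "porosity",
    spacing_mm = volume$spacing_mm,
    dim = d,
    value_min = lo,
    value_max = hi,
    clipped = if (!is_grey) volume$clipped else NULL,
    format = format
  )
  if (format == "tiff_stack") {
    pages <- lapply(seq_len(d[1]), function(s) matrix(scaled[s, , ], d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    sidecar_path <- paste0(path, ".json")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_len(d[1])) {
      utils::write.table(
        matrix(arr[s, , ], d[2], d[3]),
        file.path(path, sprintf("slice_%04d.csv", s)),
        sep = ",", row.names = FALSE, col.names = FALSE
      )
    }
    sidecar_path <- file.path(path, "volume.json")
  }
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = c("tiff_stack", "csv_slices")) {
  if (!is.character(format) || !all(format %in% c("tiff_stack", "csv_slices"))) {
    abort("unknown format")
  }
  format <- match.arg(format)
  sidecar_path <- if (format == "tiff_stack") paste0(path, ".json") else {
    file.path(path, "volume.json")
  }
  if (!file.exists(sidecar_path)) abort("missing volume sidecar metadata")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  arr <- array(0, d)
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[1]) abort("slice count mismatch")
    for (s in seq_len(d[1])) {
      arr[s, , ] <- pages[[s]] * (meta$value_max - meta$value_min) +
        meta$value_min
    }
  } else {
    files <- sort(list.files(path, pattern = "^slice_\\d+\\.csv$",
                             full.names = TRUE))
    if (length(files) != d[1]) abort("slice count mismatch")
    for (s in seq_len(d[1])) {
      arr[s, , ] <- as.matrix(utils::read.table(files[s], sep = ","))
    }
  }
  if (identical(meta$kind, "grey")) {
    grey_volume(round(arr), meta$spacing_mm)
  } else {
    porosity_volume(arr, meta$spacing_mm, clipped = isTRUE(meta$clipped))
  }
}

#' Write tabular metrics as delimited text
#'
#' Writes records with a header row, a deterministic column order (the order
#' of the first record) and locale-independent decimal points. Accepts a
#' data frame or a list of same-schema named lists; a list with diverging
#' field names is a schema mismatch error. An empty record list still
#' produces the header when column names are supplied via an empty data
#' frame.
#'
#' @param records data frame / tibble, or list of named lists sharing one
#'   schema.
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, sep = ",") {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L) abort("empty record list without schema")
    schemas <- lapply(records, names)
    if (any(vapply(schemas, function(s) !identical(s, schemas[[1]]), TRUE))) {
      abort("schema mismatch")
    }
    df <- dplyr::bind_rows(lapply(records, as_tibble))
  } else {
    abort("`records` must be a data frame or list of named lists")
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}
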