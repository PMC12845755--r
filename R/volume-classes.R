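#' Volumetric CT containers
#'
#' `grey_volume()` wraps a reconstructed CT volume of signed 16-bit grey
#' values; `porosity_volume()` wraps a voxelwise porosity map in percent.
#' Both carry the voxel spacing in millimetres and use the axis order
#' `(slice, row, col)` throughout the package. The physical centre of voxel
#' `i` along an axis with spacing `h` is at `(i - 0.5) * h` mm, so a volume
#' spans `[0, n * h]` mm along that axis.
#'
#' @param voxels 3D array of grey values; must lie in the signed 16-bit
#'   range \[-32768, 32767\].
#' @param spacing_mm numeric triple `(slice, row, col)` of voxel spacings in
#'   mm; all strictly positive and finite.
#' @param series_meta free-form named list of acquisition metadata.
#' @return An object of class `grey_volume` (resp. `porosity_volume`): a
#'   list with elements `voxels` (resp. `porosity`), `spacing_mm` and
#'   metadata.
#' @examples
#' v <- grey_volume(array(49L, c(4, 4, 4)), c(0.5, 0.339, 0.339))
#' v
#' @export
grey_volume <- function(voxels, spacing_mm, series_meta = list()) {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.")
  }
  if (anyNA(voxels)) abort("`voxels` must not contain NA.")
  rng <- range(voxels)
  if (rng[1] < -32768 || rng[2] > 32767) {
    abort("grey values must lie in the signed 16-bit range [-32768, 32767]")
  }
  spacing_mm <- check_spacing(spacing_mm)
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, series_meta = series_meta),
    class = "grey_volume"
  )
}

#' @rdname grey_volume
#' @param porosity 3D numeric array of porosity values in percent.
#' @param clipped logical; `TRUE` when values have been clamped to
#'   \[0, 100\].
#' @export
porosity_volume <- function(porosity, spacing_mm, clipped = FALSE) {
  if (length(dim(porosity)) != 3L) {
    abort("`porosity` must be a 3D array.")
  }
  spacing_mm <- check_spacing(spacing_mm)
  if (isTRUE(clipped)) {
    rng <- range(porosity)
    if (rng[1] < 0 || rng[2] > 100) {
      abort("clipped porosity volume has values outside [0, 100]")
    }
  }
  storage.mode(porosity) <- "double"
  structure(
    list(porosity = porosity, spacing_mm = spacing_mm,
         clipped = isTRUE(clipped)),
    class = "porosity_volume"
  )
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be three strictly positive finite values")
  }
  spacing_mm
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<grey_volume> %d x %d x %d voxels (slice, row, col), spacing %s mm\n",
    d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x ")
  ))
  cat(sprintf("  grey range [%d, %d]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.porosity_volume <- function(x, ...) {
  d <- dim(x$porosity)
  cat(sprintf(
    "<porosity_volume> %d x %d x %d voxels, spacing %s mm%s\n",
    d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x "),
    if (x$clipped) ", clipped to [0, 100]" else ""
  ))
  cat(sprintf("  porosity range [%.2f, %.2f] %%\n",
              min(x$porosity), max(x$porosity)))
  invisible(x)
}

#' @export
dim.grey_volume <- function(x) dim(x$voxels)

#' @export
dim.porosity_volume <- function(x) dim(x$porosity)

vol_array <- function(x) {
  if (inherits(x, "grey_volume")) return(x$voxels)
  if (inherits(x, "porosity_volume")) return(x$porosity)
  if (is.array(x)) return(x)
  abort("expected a grey_volume, porosity_volume or 3D array")
}

vol_spacing <- function(x) {
  if (is.list(x) && !is.null(x$spacing_mm)) return(x$spacing_mm)
  abort("object carries no `spacing_mm`")
}

voxel_volume_mm3 <- function(x) prod(vol_spacing(x))

# voxel-centre coordinates (mm) for 1-based indices along one axis
axis_mm <- function(idx, spacing) (idx - 0.5) * spacing
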