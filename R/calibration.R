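#' Two-point grey-value to porosity calibration
#'
#' Fits the unique line through two reference measurements: the grey value of
#' juice (0% porosity, i.e. fully liquid tissue) and the grey value of air
#' (100% porosity). The model is
#' `porosity = slope * grey + intercept` with
#' `slope = 100 / (air_grey - juice_grey)` and
#' `intercept = -slope * juice_grey`. It is deliberately unclamped so that
#' out-of-range voxels (e.g. dense seeds) remain diagnosable; clamping is an
#' explicit option of [apply_calibration()].
#'
#' The shipped defaults are the reference pair measured on 'Gala' apple
#' juice (grey 49) and external air (grey -1007) on the signed 16-bit scale;
#' both anchors should be re-measured when calibrating other cultivars or
#' scanners.
#'
#' @param juice_grey grey value of the 0%-porosity reference (juice).
#' @param air_grey grey value of the 100%-porosity reference (air).
#' @return A `porosity_calibration` object: list with `juice_grey`,
#'   `air_grey`, `slope` (% per grey unit), `intercept` (% at grey 0) and
#'   `r_squared` (`NA` until validated).
#' @examples
#' cal <- fit_two_point()
#' predict(cal, c(49, -1007, -479))
#' @export
fit_two_point <- function(juice_grey = 49, air_grey = -1007) {
  check_int16(juice_grey, "juice_grey")
  check_int16(air_grey, "air_grey")
  if (juice_grey == air_grey) {
    abort("degenerate calibration: juice_grey and air_grey must differ")
  }
  slope <- 100 / (air_grey - juice_grey)
  structure(
    list(
      juice_grey = juice_grey,
      air_grey = air_grey,
      slope = slope,
      intercept = -slope * juice_grey,
      r_squared = NA_real_
    ),
    class = "porosity_calibration"
  )
}

check_int16 <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < -32768 || x > 32767) {
    abort(sprintf("`%s` must be a single grey value in [-32768, 32767]", name))
  }
}

#' @export
print.porosity_calibration <- function(x, ...) {
  cat(sprintf(
    "<porosity_calibration> porosity %% = %.6g * grey + %.6g\n",
    x$slope, x$intercept
  ))
  cat(sprintf("  anchors: juice %d -> 0%%, air %d -> 100%%\n",
              as.integer(x$juice_grey), as.integer(x$air_grey)))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  validation R-squared: %.4f\n", x$r_squared))
  }
  invisible(x)
}

#' @export
#' @param object,newdata standard [stats::predict()] arguments; `newdata` is
#'   a numeric vector of grey values.
#' @param ... unused.
#' @rdname fit_two_point
predict.porosity_calibration <- function(object, newdata, ...) {
  object$slope * as.numeric(newdata) + object$intercept
}

#' Convert a grey-value volume to a porosity map
#'
#' Applies the affine calibration voxelwise. With `clip = TRUE` (the
#' default for reporting maps) values are clamped to \[0, 100\] and the
#' result is flagged as clipped; with `clip = FALSE` the raw extrapolated
#' values are preserved.
#'
#' @param volume a [grey_volume()].
#' @param calib a [fit_two_point()] calibration.
#' @param clip clamp to \[0, 100\]?
#' @return A [porosity_volume()] of the same shape and spacing.
#' @export
apply_calibration <- function(volume, calib, clip = TRUE) {
  stopifnot(inherits(volume, "grey_volume"),
            inherits(calib, "porosity_calibration"))
  p <- calib$slope * volume$voxels + calib$intercept
  if (isTRUE(clip)) {
    p[p < 0] <- 0
    p[p > 100] <- 100
  }
  dim(p) <- dim(volume$voxels)
  porosity_volume(p, volume$spacing_mm, clipped = isTRUE(clip))
}

#' Validate a calibration by random voxel sampling
#'
#' Samples `n` voxels uniformly without replacement (seeded), predicts their
#' porosity from the grey volume through the calibration, and compares
#' against a reference porosity volume, reporting the coefficient of
#' determination. This mirrors the protocol of spot-checking a small number
#' of pixels against reference porosity; with synthetic phantoms the truth
#' volume is exact.
#'
#' @param volume a [grey_volume()].
#' @param truth a [porosity_volume()] of the same shape holding reference
#'   porosity.
#' @param calib a [fit_two_point()] calibration.
#' @param n number of voxels to sample (default 10).
#' @param seed RNG seed for reproducible sampling.
#' @return A `calibration_validation` object: list with `samples` (tibble of
#'   coordinates, predicted and true porosity) and `r_squared`.
#' @export
validate_by_sampling <- function(volume, truth, calib, n = 10, seed = 1L) {
  stopifnot(inherits(volume, "grey_volume"),
            inherits(truth, "porosity_volume"),
            inherits(calib, "porosity_calibration"))
  d <- dim(volume$voxels)
  if (!identical(d, dim(truth$porosity))) {
    abort("`volume` and `truth` must share shape")
  }
  nvox <- prod(d)
  if (n < 2) abort("`n` must be >= 2")
  if (n > nvox) abort("sample too large: n exceeds voxel count")
  idx <- with_seed(seed, sample.int(nvox, n))
  co <- arrayInd(idx, d)
  predicted <- predict(calib, volume$voxels[idx])
  true <- truth$porosity[idx]
  ss_res <- sum((true - predicted)^2)
  ss_tot <- sum((true - mean(true))^2)
  r2 <- if (ss_res <= .Machine$double.eps * max(1, ss_tot)) {
    1
  } else if (ss_tot == 0) {
    NA_real_  # constant truth with prediction error: R^2 undefined
  } else {
    1 - ss_res / ss_tot
  }
  structure(
    list(
      samples = tibble(
        slice = co[, 1], row = co[, 2], col = co[, 3],
        grey = as.numeric(volume$voxels[idx]),
        predicted = predicted, true = true
      ),
      r_squared = r2, n = n, seed = seed
    ),
    class = "calibration_validation"
  )
}

#' @export
print.calibration_validation <- function(x, ...) {
  cat(sprintf("<calibration_validation> n = %d, R-squared = %s\n",
              x$n, format(x$r_squared, digits = 4)))
  print(head(x$samples, 5))
  invisible(x)
}

#' Serialize / restore a calibration as JSON
#'
#' @param calib a `porosity_calibration`.
#' @param path file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the restored `porosity_calibration`.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "porosity_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- fit_two_point(x$juice_grey, x$air_grey)
  cal$r_squared <- x$r_squared %||% NA_real_
  cal
}

# run code under a temporary RNG state seeded with `seed`; the seed promise
# is forced first so callers may compute it from the outer RNG stream
with_seed <- function(seed, code) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
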