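# broom-style tidiers for the fitted objects.

#' @export
tidy.porosity_calibration <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @export
glance.porosity_calibration <- function(x, ...) {
  tibble(
    juice_grey = x$juice_grey,
    air_grey = x$air_grey,
    r_squared = x$r_squared
  )
}

#' @export
tidy.calibration_validation <- function(x, ...) x$samples

#' @export
glance.calibration_validation <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, seed = x$seed)
}

#' @export
tidy.group_comparison <- function(x, ...) x$tukey

#' @export
glance.group_comparison <- function(x, ...) x$anova

#' @export
tidy.quality_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "parameter") |>
    tidyr::pivot_longer(-"parameter", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.quality_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$variance_fraction)),
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}

#' @export
tidy.fruit_masks <- function(x, ...) x$fruits

#' @export
tidy.region_labels <- function(x, ...) x$counts
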