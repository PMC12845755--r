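# Macro-scale porosity summaries: whole-fruit and regional means, slice
# maps, line profiles, treatment comparisons and macro-micro correlation.

#' Whole-fruit mean porosity
#'
#' Arithmetic mean of the porosity map over each fruit mask. Gas-filled
#' cavities count toward the whole-fruit mean by default (they are part of
#' the fruit's internal air space); set `include_cavity = FALSE` and supply
#' `regions` to restrict the mean to non-cavity tissue.
#'
#' @param pmap a [porosity_volume()].
#' @param masks a `fruit_masks` from [segment_fruits()].
#' @param include_cavity include cavity voxels (default `TRUE`)?
#' @param regions a `region_labels`; required when `include_cavity = FALSE`.
#' @return A tibble with `fruit`, `mean_porosity` (percent) and `n_voxels`.
#' @export
whole_fruit_porosity <- function(pmap, masks, include_cavity = TRUE,
                                 regions = NULL) {
  stopifnot(inherits(pmap, "porosity_volume"), inherits(masks, "fruit_masks"))
  d <- dim(pmap$porosity)
  if (!identical(d, dim(masks$labels))) abort("pmap and masks must share shape")
  if (masks$fruit_count == 0L) abort("no fruit voxels")
  if (!include_cavity && is.null(regions)) {
    abort("`regions` is required when include_cavity = FALSE")
  }
  purrr::map_dfr(seq_len(masks$fruit_count), function(f) {
    sel <- masks$labels == f
    if (!include_cavity) {
      sel <- sel & regions$regions != REGION_LEVELS[["cavity"]]
    }
    n <- sum(sel)
    if (n == 0L) abort("no fruit voxels")
    tibble(fruit = f, mean_porosity = mean(pmap$porosity[sel]), n_voxels = n)
  })
}

#' Porosity line profile
#'
#' Samples the porosity map at `n_samples` equally spaced points on the
#' segment from `start_mm` to `end_mm` (physical coordinates, axis order
#' slice/row/col) using trilinear interpolation between voxel centres.
#'
#' @param pmap a [porosity_volume()].
#' @param start_mm,end_mm numeric triples in mm.
#' @param n_samples number of sample points (>= 2).
#' @return A tibble with `position_mm` (distance from `start_mm`) and
#'   `porosity`.
#' @export
line_profile <- function(pmap, start_mm, end_mm, n_samples = 100) {
  stopifnot(inherits(pmap, "porosity_volume"), n_samples >= 2)
  d <- dim(pmap$porosity)
  sp <- pmap$spacing_mm
  for (pt in list(start_mm, end_mm)) {
    if (length(pt) != 3L || any(pt < 0) || any(pt > d * sp)) {
      abort("profile outside volume")
    }
  }
  tt <- seq(0, 1, length.out = n_samples)
  pts <- outer(tt, end_mm - start_mm) + rep(start_mm, each = n_samples)
  vals <- trilinear(pmap$porosity, pts, sp)
  tibble(
    position_mm = tt * sqrt(sum((end_mm - start_mm)^2)),
    porosity = vals
  )
}

# trilinear interpolation at physical points (rows of pts), cell-centred
# grid; fractional indices clamped to [1, n] so queries within the outer
# half-voxel use the boundary value
trilinear <- function(arr, pts, sp) {
  d <- dim(arr)
  fi <- sweep(pts, 2, sp, "/") + 0.5  # fractional voxel index
  fi <- pmin(pmax(fi, 1), matrix(d, nrow(pts), 3, byrow = TRUE))
  lo <- floor(fi)
  lo <- pmin(lo, matrix(d - 1L, nrow(pts), 3, byrow = TRUE))
  lo <- pmax(lo, 1)
  w <- fi - lo
  v <- numeric(nrow(pts))
  for (ds in 0:1) for (dr in 0:1) for (dc in 0:1) {
    wt <- (if (ds) w[, 1] else 1 - w[, 1]) *
      (if (dr) w[, 2] else 1 - w[, 2]) *
      (if (dc) w[, 3] else 1 - w[, 3])
    idx <- cbind(lo[, 1] + ds, lo[, 2] + dr, lo[, 3] + dc)
    v <- v + wt * arr[idx]
  }
  v
}

#' Extract a 2D porosity slice map
#'
#' @param pmap a [porosity_volume()].
#' @param axis `"slice"`, `"row"` or `"col"`: the axis normal to the plane.
#' @param index 1-based position along `axis`.
#' @return A `porosity_slice`: the 2D matrix plus in-plane axis names and
#'   spacings; supports [autoplot()].
#' @export
slice_porosity_map <- function(pmap, axis = c("slice", "row", "col"), index) {
  stopifnot(inherits(pmap, "porosity_volume"))
  axis <- match.arg(axis)
  d <- dim(pmap$porosity)
  ax <- match(axis, c("slice", "row", "col"))
  if (index < 1 || index > d[ax]) abort("index out of range")
  m <- switch(axis,
    slice = pmap$porosity[index, , ],
    row = pmap$porosity[, index, ],
    col = pmap$porosity[, , index]
  )
  keep <- setdiff(1:3, ax)
  structure(
    list(values = m, axis = axis, index = index,
         plane_axes = c("slice", "row", "col")[keep],
         plane_spacing_mm = pmap$spacing_mm[keep]),
    class = "porosity_slice"
  )
}

#' @export
print.porosity_slice <- function(x, ...) {
  cat(sprintf("<porosity_slice> %s = %d, %d x %d map (%s)\n", x$axis,
              x$index, nrow(x$values), ncol(x$values),
              paste(x$plane_axes, collapse = " x ")))
  invisible(x)
}

#' Per-region porosity summary
#'
#' Mean, SD and voxel count of the porosity map per fruit and region.
#' Regions absent from a fruit are reported with count 0 and `NA` mean/SD.
#'
#' @param pmap a [porosity_volume()].
#' @param regions a `region_labels` from [classify_regions()].
#' @param masks a `fruit_masks`; when omitted, regions are summarized over
#'   the whole volume as a single fruit.
#' @return A tibble with `fruit`, `region`, `mean_porosity`, `sd_porosity`,
#'   `n_voxels`.
#' @export
regional_summary <- function(pmap, regions, masks = NULL) {
  stopifnot(inherits(pmap, "porosity_volume"),
            inherits(regions, "region_labels"))
  d <- dim(pmap$porosity)
  if (!identical(d, dim(regions$regions))) {
    abort("pmap and regions must share shape")
  }
  labels <- if (!is.null(masks)) masks$labels else {
    regions$fruit_labels %||% (regions$regions > 0L) * 1L
  }
  fruit_ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  region_names <- names(REGION_LEVELS)[-1]
  purrr::map_dfr(fruit_ids, function(f) {
    purrr::map_dfr(region_names, function(rg) {
      sel <- labels == f & regions$regions == REGION_LEVELS[[rg]]
      n <- sum(sel)
      tibble(
        fruit = f, region = rg,
        mean_porosity = if (n > 0) mean(pmap$porosity[sel]) else NA_real_,
        sd_porosity = if (n > 1) sd(pmap$porosity[sel]) else NA_real_,
        n_voxels = n
      )
    })
  })
}

#' One-way ANOVA with Tukey HSD over treatment groups
#'
#' Standard one-way analysis of variance of a per-fruit response across
#' treatment levels, with Tukey honest-significant-difference pairwise
#' intervals at the given confidence level.
#'
#' @param data data frame of per-fruit values.
#' @param value,group column names (strings) of the response and the
#'   grouping factor.
#' @param conf_level confidence level for the Tukey intervals (default
#'   0.95).
#' @return A `group_comparison` object: `anova` (tibble with `f_statistic`,
#'   `p_value`, degrees of freedom), `tukey` (pairwise tibble) and the group
#'   means; supports [tidy()] and [glance()].
#' @export
compare_groups <- function(data, value, group, conf_level = 0.95) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  df <- data.frame(y = as.numeric(data[[value]]),
                   g = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  sizes <- table(df$g)
  if (length(sizes) < 2L) abort("need >= 2 groups")
  if (any(sizes < 2L)) abort("insufficient replication: a group has n < 2")
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf_level)$g
  structure(
    list(
      anova = tibble(
        f_statistic = an[["F value"]][1],
        p_value = an[["Pr(>F)"]][1],
        df_between = an[["Df"]][1],
        df_within = an[["Df"]][2]
      ),
      tukey = tibble(
        contrast = rownames(tk),
        difference = tk[, "diff"],
        conf_low = tk[, "lwr"],
        conf_high = tk[, "upr"],
        p_adjusted = tk[, "p adj"]
      ),
      means = df |>
        dplyr::group_by(.data$g) |>
        dplyr::summarise(mean = mean(.data$y), n = dplyr::n(),
                         .groups = "drop") |>
        dplyr::rename(group = "g"),
      conf_level = conf_level
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within,
              x$anova$f_statistic, x$anova$p_value))
  print(x$tukey)
  invisible(x)
}

#' Correlation between macro-scale porosity and microstructure
#'
#' Reports both Pearson (linear) and Spearman (rank) correlations with
#' p-values for paired per-sample measurements, e.g. whole-fruit macro
#' porosity against a cellular-scale metric. Constant input yields an
#' `NA` estimate marker rather than an error.
#'
#' @param macro,micro paired numeric vectors (n >= 3).
#' @return A tibble with one row per method: `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
macro_micro_correlation <- function(macro, micro) {
  macro <- as.numeric(macro)
  micro <- as.numeric(micro)
  if (length(macro) != length(micro)) abort("vectors must be paired")
  ok <- complete.cases(macro, micro)
  macro <- macro[ok]; micro <- micro[ok]
  if (length(macro) < 3L) abort("need >= 3 paired samples")
  one <- function(method) {
    if (sd(macro) == 0 || sd(micro) == 0) {
      return(tibble(method = method, estimate = NA_real_,
                    p_value = NA_real_, n = length(macro)))
    }
    ct <- suppressWarnings(cor.test(macro, micro, method = method))
    tibble(method = method, estimate = unname(ct$estimate),
           p_value = ct$p.value, n = length(macro))
  }
  dplyr::bind_rows(one("pearson"), one("spearman"))
}
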