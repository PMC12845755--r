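# Composite quality index: Z-score standardization, PCA of the trait
# correlation structure, loading-derived weights, the weighted index Q,
# loading-dominance groups and radar-chart export.

quality_param_cols <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("unknown parameter column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(cols) < 2L) abort("need >= 2 parameters")
  cols
}

#' Z-score standardization of quality parameters
#'
#' Standardizes each parameter column to `z = (x - mu) / sigma`. The default
#' uses the population standard deviation (divisor `n`); `mode = "sample"`
#' uses the usual `n - 1` divisor. Non-numeric columns pass through
#' unchanged. Rows with missing parameter values are dropped with a warning.
#'
#' @param data data frame of samples by parameters.
#' @param cols parameter columns (default: all numeric columns).
#' @param mode `"population"` or `"sample"` standard deviation.
#' @return A tibble of the same shape with standardized parameter columns;
#'   attributes `mu` and `sigma` store the column statistics.
#' @export
zscore <- function(data, cols = NULL, mode = c("population", "sample")) {
  mode <- match.arg(mode)
  cols <- quality_param_cols(data, cols)
  keep <- complete.cases(data[cols])
  if (!all(keep)) {
    warn(sprintf("dropped %d row(s) with missing parameter values",
                 sum(!keep)))
    data <- data[keep, ]
  }
  if (nrow(data) < 2L) abort("need >= 2 samples")
  out <- as_tibble(data)
  mu <- vapply(out[cols], mean, 0)
  sigma <- vapply(out[cols], function(x) {
    s2 <- if (mode == "population") mean((x - mean(x))^2) else var(x)
    sqrt(s2)
  }, 0)
  if (any(sigma == 0)) {
    abort(sprintf("zero variance column: %s",
                  paste(cols[sigma == 0], collapse = ", ")))
  }
  for (j in seq_along(cols)) {
    out[[cols[j]]] <- (out[[cols[j]]] - mu[j]) / sigma[j]
  }
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "z_cols") <- cols
  attr(out, "ddof_mode") <- mode
  out
}

#' PCA of a standardized quality table
#'
#' Eigendecomposition of the correlation structure of the standardized
#' parameters (principal components of the z-matrix, no further scaling).
#' Component signs are fixed so that the largest-magnitude loading of each
#' component is positive, making results reproducible across platforms.
#'
#' @param z a standardized table from [zscore()] (or any data frame of
#'   z-scored columns).
#' @param cols parameter columns (default: the [zscore()] columns, else all
#'   numeric columns).
#' @return A `quality_pca`: `loadings` (parameters x components),
#'   `variance_fraction`, `scores` (tibble), `sdev`. Supports [tidy()] /
#'   [glance()].
#' @export
quality_pca <- function(z, cols = NULL) {
  cols <- attr(z, "z_cols") %||% cols
  cols <- quality_param_cols(z, cols)
  m <- as.matrix(z[cols])
  if (any(!is.finite(m))) abort("z-matrix must be finite")
  if (all(apply(m, 2, sd) == 0)) abort("degenerate: rank-0 matrix")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      loadings = load,
      variance_fraction = vf,
      sdev = pc$sdev,
      scores = as_tibble(pc$x),
      parameters = cols
    ),
    class = "quality_pca"
  )
}

#' @export
print.quality_pca <- function(x, ...) {
  k <- min(3L, length(x$variance_fraction))
  cat(sprintf(
    "<quality_pca> %d parameters; variance fractions: %s\n",
    nrow(x$loadings),
    paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_fraction[1:k]),
          collapse = ", ")
  ))
  invisible(x)
}

#' Derive quality weights from PCA loadings
#'
#' The default strategy weights each parameter by the sum over the first `k`
#' components of its absolute loading times the component's explained
#' variance fraction, normalized to sum to one. The `"pc1_only"` strategy
#' uses the absolute first-component loadings alone. Weights are therefore
#' nonnegative and sum to one exactly.
#'
#' @param pca a [quality_pca()].
#' @param k number of leading components to use (default 2).
#' @param strategy `"loading_x_variance"` (default) or `"pc1_only"`.
#' @return A `quality_weights`: tibble with `parameter`, `weight`, plus
#'   provenance attributes (`k`, `strategy`, variance fractions used).
#' @export
derive_weights <- function(pca, k = 2,
                           strategy = c("loading_x_variance", "pc1_only")) {
  stopifnot(inherits(pca, "quality_pca"))
  strategy <- match.arg(strategy)
  if (k > ncol(pca$loadings)) abort("k exceeds the number of components")
  raw <- if (strategy == "pc1_only") {
    abs(pca$loadings[, 1])
  } else {
    as.vector(abs(pca$loadings[, seq_len(k), drop = FALSE]) %*%
                pca$variance_fraction[seq_len(k)])
  }
  if (sum(raw) == 0) abort("degenerate weights: all loadings zero")
  w <- raw / sum(raw)
  out <- tibble(parameter = rownames(pca$loadings), weight = unname(w))
  attr(out, "k") <- k
  attr(out, "strategy") <- strategy
  attr(out, "variance_fraction") <- pca$variance_fraction[seq_len(k)]
  class(out) <- c("quality_weights", class(out))
  out
}

#' Composite quality index Q
#'
#' Per-sample weighted sum of standardized parameters:
#' `Q = sum_i w_i * z_i`. With fixed weights and z-scored columns the mean
#' of Q over samples is zero, so Q expresses each sample's overall quality
#' relative to the cohort.
#'
#' @param z standardized table from [zscore()].
#' @param weights a [derive_weights()] table (or any tibble with `parameter`
#'   and `weight`).
#' @return A tibble: the non-parameter identifier columns of `z` plus `Q`.
#' @export
quality_score <- function(z, weights) {
  cols <- attr(z, "z_cols") %||%
    names(z)[vapply(z, is.numeric, TRUE)]
  if (!setequal(weights$parameter, cols)) {
    abort("weight/parameter mismatch")
  }
  w <- setNames(weights$weight, weights$parameter)[cols]
  q <- as.vector(as.matrix(z[cols]) %*% w)
  id_cols <- setdiff(names(z), cols)
  dplyr::bind_cols(as_tibble(z[id_cols]), tibble(Q = q))
}

#' Assign parameters to loading-dominance groups
#'
#' With two leading components, a parameter belongs to group A when its
#' absolute PC1 loading exceeds its absolute PC2 loading by more than
#' `dominance_margin`, to group C when PC2 dominates by the same margin, and
#' to group B otherwise (comparable loadings on both axes).
#'
#' @param pca a [quality_pca()].
#' @param dominance_margin required loading-dominance margin (default 0.2).
#' @return A tibble with `parameter`, `group` (factor A/B/C), and the two
#'   absolute loadings.
#' @export
assign_groups <- function(pca, dominance_margin = 0.2) {
  stopifnot(inherits(pca, "quality_pca"))
  if (ncol(pca$loadings) < 2L) abort("need at least two components")
  l1 <- abs(pca$loadings[, 1])
  l2 <- abs(pca$loadings[, 2])
  group <- ifelse(l1 - l2 > dominance_margin, "A",
                  ifelse(l2 - l1 > dominance_margin, "C", "B"))
  tibble(
    parameter = rownames(pca$loadings),
    group = factor(group, levels = c("A", "B", "C")),
    abs_loading_pc1 = unname(l1),
    abs_loading_pc2 = unname(l2)
  )
}

#' Radar-chart export of per-treatment parameter means
#'
#' Computes the mean of every parameter per treatment level and min-max
#' scales each parameter to \[0, 1\] across levels (the level with the
#' highest mean scores 1). Axes are ordered by group (A block, then B, then
#' C; alphabetical within a block). Parameters whose means are equal across
#' all levels cannot be scaled; they are set to 0 and flagged.
#'
#' @param data quality table (raw values).
#' @param groups group assignment tibble from [assign_groups()].
#' @param treatment name of the treatment column in `data` (>= 2 levels).
#' @return A tibble with `level`, `parameter` (ordered factor), `group`,
#'   `mean_value`, `value` (scaled), `degenerate` flag.
#' @export
radar_export <- function(data, groups, treatment) {
  stopifnot(is.data.frame(data), treatment %in% names(data))
  lv <- unique(as.character(data[[treatment]]))
  if (length(lv) < 2L) abort("nothing to compare: single treatment level")
  ord <- groups |>
    dplyr::arrange(.data$group, .data$parameter) |>
    dplyr::pull("parameter")

  data |>
    dplyr::group_by(level = as.character(.data[[treatment]])) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(ord), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"level", names_to = "parameter",
                        values_to = "mean_value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(
      degenerate = max(.data$mean_value) == min(.data$mean_value),
      value = dplyr::if_else(
        .data$degenerate, 0,
        (.data$mean_value - min(.data$mean_value)) /
          (max(.data$mean_value) - min(.data$mean_value))
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::left_join(groups[c("parameter", "group")], by = "parameter") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = ord)) |>
    dplyr::arrange(.data$parameter, .data$level)
}

#' @export
print.quality_weights <- function(x, ...) {
  cat(sprintf("<quality_weights> strategy %s, k = %d\n",
              attr(x, "strategy"), attr(x, "k")))
  NextMethod()
}
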