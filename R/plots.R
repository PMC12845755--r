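# ggplot2 helpers for the main result types.

#' Plot a 2D porosity slice map
#'
#' @param object a `porosity_slice` from [slice_porosity_map()].
#' @param ... unused.
#' @return A ggplot object (filled raster in physical mm coordinates).
#' @export
autoplot.porosity_slice <- function(object, ...) {
  df <- expand.grid(
    i = seq_len(nrow(object$values)),
    j = seq_len(ncol(object$values))
  )
  df$x <- axis_mm(df$j, object$plane_spacing_mm[2])
  df$y <- axis_mm(df$i, object$plane_spacing_mm[1])
  df$porosity <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$porosity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "porosity (%)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s (mm)", object$plane_axes[2]),
      y = sprintf("%s (mm)", object$plane_axes[1]),
      title = sprintf("Porosity map, %s %d", object$axis, object$index)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a porosity line profile
#'
#' @param profile tibble from [line_profile()].
#' @return A ggplot object.
#' @export
plot_line_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position_mm,
                                        y = .data$porosity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)", y = "porosity (%)") +
    ggplot2::theme_minimal()
}

#' Radar chart of per-treatment quality profiles
#'
#' Displays the min-max scaled parameter means from [radar_export()] on a
#' polar axis, one line per treatment level, axes ordered by anatomical
#' group.
#'
#' @param radar tibble from [radar_export()].
#' @return A ggplot object.
#' @export
plot_radar <- function(radar) {
  ggplot2::ggplot(radar, ggplot2::aes(x = .data$parameter, y = .data$value,
                                      group = .data$level,
                                      colour = .data$level)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = "level") +
    ggplot2::theme_minimal()
}

#' Biplot-style view of a quality PCA
#'
#' @param object a [quality_pca()].
#' @param ... unused.
#' @return A ggplot object showing parameter loadings on the first two
#'   components.
#' @export
autoplot.quality_pca <- function(object, ...) {
  df <- tibble(
    parameter = rownames(object$loadings),
    pc1 = object$loadings[, 1],
    pc2 = if (ncol(object$loadings) > 1) object$loadings[, 2] else 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   label = .data$parameter)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_text(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = if (length(object$variance_fraction) > 1) {
        sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])
      } else "PC2"
    ) +
    ggplot2::theme_minimal()
}
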