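# ggplot2 views of the result objects.

#' Plot a density map as a projection heat map
#'
#' Maximum (or sum) projection of the coarse cell-volume field along one
#' axis.
#'
#' @param object A [density_map()].
#' @param axis Projection axis: `"z"` (default), `"y"` or `"x"`.
#' @param fun Projection: `"max"` (default) or `"sum"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, axis = c("z", "y", "x"),
                                 fun = c("max", "sum"), ...) {
  axis <- match.arg(axis)
  fun <- match.arg(fun)
  margin <- setdiff(1:3, match(axis, c("z", "y", "x")))
  proj <- apply(object$grid, margin, if (fun == "max") max else sum)
  df <- tidyr::expand_grid(row = seq_len(nrow(proj)), col = seq_len(ncol(proj)))
  df$volume <- proj[cbind(df$row, df$col)]
  lab <- c("z", "y", "x")[margin]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$volume)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression("cell volume (" * mu * m^3 * ")")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = sprintf("%s (%.3g um voxels)", lab[2], object$spacing[1]),
      y = sprintf("%s (%.3g um voxels)", lab[1], object$spacing[1]),
      title = sprintf("Detected cell volume, %s projection along %s", fun, axis)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-region cell volume by group
#'
#' Bar chart of group mean regional cell volume with +/- SD error bars
#' (single-sample groups are drawn without a bar whisker).
#'
#' @param object A [region_report()].
#' @param include_unassigned Keep the `"unassigned"` bucket (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_report
#' @export
autoplot.region_report <- function(object, include_unassigned = FALSE, ...) {
  stats_tbl <- group_stats(object)
  if (!include_unassigned) {
    stats_tbl <- stats_tbl[stats_tbl$region != "unassigned", ]
  }
  ggplot2::ggplot(stats_tbl,
                  ggplot2::aes(x = stats::reorder(.data$region,
                                                  -.data$mean_volume_um3),
                               y = .data$mean_volume_um3,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_volume_um3 -
                     ifelse(is.na(.data$sd_volume_um3), 0, .data$sd_volume_um3),
                   ymax = .data$mean_volume_um3 +
                     ifelse(is.na(.data$sd_volume_um3), 0, .data$sd_volume_um3)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = expression("cell volume (" * mu * m^3 * ")"),
                  title = "Regional cell volume, group mean ± SD") +
    ggplot2::theme_minimal()
}

#' Plot the TP/TN convergence series
#'
#' @param object A `validation_report` from [convergence_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  series <- tidy(object)
  long <- tidyr::pivot_longer(series, c("tp_fraction", "tn_fraction"),
                              names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_discrete(
      labels = c(tp_fraction = "TP % of true cell volume",
                 tn_fraction = "TN % of true non-cell volume")
    ) +
    ggplot2::labs(x = "z-slices included", y = "percent", colour = NULL,
                  title = "Validation metric convergence over z") +
    ggplot2::theme_minimal()
}
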