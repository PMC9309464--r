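#' Plot a landscape's AGC raster
#'
#' @param object A `zos_landscape`.
#' @param value Column to plot (`"agc"`, `"capacity"`, ...).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zos_landscape <- function(object, value = "agc", ...) {
  ggplot2::ggplot(object[!is.na(object$agc), ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-year trajectories of a simulation result
#'
#' Replicate-mean trajectories (with replicate spaghetti underneath) of the
#' focal species' population size, heterozygosity and mean habitat traits.
#'
#' @param object A `zos_result`.
#' @param ... Unused.
#' @return A ggplot, facetted by variable.
#' @export
autoplot.zos_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$years,
                              c("n_adults", "heterozygosity",
                                "mean_agc_optimum", "mean_agc_tolerance"),
                              names_to = "variable")
  means <- long |>
    dplyr::group_by(.data$variable, .data$year) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = means, colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-patch map (density or heterozygosity)
#'
#' @param map Tibble with `row`, `col` and a value column, as returned by
#'   [density_map()] or [patch_heterozygosity()].
#' @param value Name of the value column.
#' @param ls Optional `zos_landscape` drawn as a grey backdrop.
#' @return A ggplot.
#' @export
plot_patch_map <- function(map, value = "n", ls = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(ls)) {
    p <- p + ggplot2::geom_raster(
      data = ls[!is.na(ls$agc), ],
      ggplot2::aes(x = .data$col, y = .data$row, alpha = .data$agc),
      fill = "grey50", show.legend = FALSE)
  }
  p +
    ggplot2::geom_raster(data = map,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data[[value]])) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fragment-area regression
#'
#' @param object A `zos_fragment_fit`.
#' @param ... Unused.
#' @return A ggplot of heterozygosity against log area with the fitted line.
#' @export
autoplot.zos_fragment_fit <- function(object, ...) {
  d <- object$model$model
  ggplot2::ggplot(d, ggplot2::aes(.data$log_area, .data$heterozygosity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = coef(object$model)[1],
                         slope = coef(object$model)[2],
                         colour = "firebrick") +
    ggplot2::labs(x = "ln(fragment area, ha)", y = "heterozygosity (%)") +
    ggplot2::theme_minimal()
}
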