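#' Plate heat map of a well feature
#'
#' @param tbl Well-feature tibble with `row`, `col` and the feature.
#' @param feature Feature column to display.
#' @return A ggplot object.
#' @export
plot_plate_heatmap <- function(tbl, feature = "area_px_med") {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$col, .data$row,
                                    fill = .data[[feature]])) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse(breaks = unique(tbl$row),
                             labels = LETTERS[unique(tbl$row)]) +
    ggplot2::scale_fill_viridis_c(name = feature) +
    ggplot2::labs(x = "column", y = "row",
                  title = paste("Plate map:", feature)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of phenotype-space scores
#'
#' @param scores Projection tibble from [project_phenotypes()].
#' @param x,y Components to plot.
#' @param colour_by Column mapped to colour (default `role`).
#' @return A ggplot object.
#' @export
plot_phenotype_scores <- function(scores, x = "PC0", y = "PC1",
                                  colour_by = "role") {
  ggplot2::ggplot(filter(scores, .data$projected),
                  ggplot2::aes(.data[[x]], .data[[y]],
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = "Phenotype space") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_phenotype_space Scree/loadings overview plot.
#' @export
autoplot.phenotype_space <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$component, .data$feature,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(title = sprintf(
      "Loadings (%s of variance)",
      paste0(round(100 * object$explained_variance_fraction, 1), "%",
             collapse = " + "))) +
    ggplot2::theme_minimal()
}

#' Dose-response / hit overview plot
#'
#' Replicate-mean size z-scores per compound and dose with the hit
#' threshold line, mirroring the way primary-screen results are usually
#' browsed.
#'
#' @param hits Hit table from [call_hits()].
#' @param threshold Threshold line position.
#' @return A ggplot object.
#' @export
plot_hits <- function(hits, threshold = 0) {
  ggplot2::ggplot(hits, ggplot2::aes(factor(.data$concentration_um),
                                     .data$mean_size_z,
                                     colour = .data$hit,
                                     group = .data$compound)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compound) +
    ggplot2::labs(x = "dose (uM)", y = "mean cyst-size z",
                  title = "Hit calling (z <= 0 at any dose)") +
    ggplot2::theme_minimal()
}
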