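#' Map the drought-sensitivity field
#'
#' Raster map of per-cell sensitivity (percent yield change per unit
#' drought index); diverging palette centred on zero so losses read red.
#'
#' @param records Sensitivity records from [sensitivity_map()].
#' @param significant_only Mask non-significant cells (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_sensitivity_map <- function(records, significant_only = FALSE) {
  df <- dplyr::filter(records, is.na(.data$flag))
  if (significant_only) df <- dplyr::filter(df, .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$beta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0,
                                  name = "β (%/DI)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Crop yield sensitivity to drought") +
    ggplot2::theme_minimal()
}

#' Dot plot of determinant importance
#'
#' @param object A `drought_attribution` fit.
#' @param ... Unused.
#' @return A ggplot object: predictors ordered by importance, min-max
#'   normalized scale.
#' @method autoplot drought_attribution
#' @export
autoplot.drought_attribution <- function(object, ...) {
  imp <- attribution_importance(object)
  imp$predictor <- stats::reorder(imp$predictor, -imp$rank)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$normalized,
                                    y = .data$predictor)) +
    ggplot2::geom_point(size = 2, colour = "#2166ac") +
    ggplot2::labs(x = "Relative importance (0-1)", y = NULL,
                  title = "Determinants of drought sensitivity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot partial-dependence curves
#'
#' @param pdp Tibble from [partial_dependence()].
#' @return A ggplot object, one panel per predictor (free x scales).
#' @export
plot_partial_dependence <- function(pdp) {
  ggplot2::ggplot(pdp, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "Predictor value",
                  y = "Partial dependence of β (%/DI)") +
    ggplot2::theme_minimal()
}

#' Bar chart of harvested-area share per sensitivity bin
#'
#' @param bins Tibble from [binned_area_share()].
#' @return A ggplot object, one panel per irrigation class; the dashed line
#'   at zero separates yield loss (left) from gain (right).
#' @export
plot_area_share <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_mid, y = .data$share)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.9 * (bins$bin_hi[1] - bins$bin_lo[1])) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "Sensitivity bin (β, %/DI)",
                  y = "Share of harvested area (%)") +
    ggplot2::theme_minimal()
}
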