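#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_col geom_tile geom_smooth scale_fill_viridis_c scale_fill_gradient
#'   labs facet_wrap theme_minimal coord_equal geom_text
#' @export
ggplot2::autoplot

melt_channels <- function(image) {
  purrr::imap_dfr(image$channels, function(g, role) {
    tibble::tibble(role = role,
                   row = as.vector(row(g)), col = as.vector(col(g)),
                   intensity = as.vector(g))
  })
}

#' Plot a synthetic or acquired field
#'
#' Per-channel intensity rasters, faceted by channel role.
#'
#' @param object A `field_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.field_image <- function(object, ...) {
  df <- melt_channels(object)
  ggplot(df, aes(.data$col, .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c() +
    facet_wrap(~role) +
    coord_equal() +
    labs(x = NULL, y = NULL,
         title = sprintf("%s %s field %d", object$plate, object$well,
                         object$field)) +
    theme_minimal()
}

#' Plot a segmentation label mask
#'
#' @param object A `segmentation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.segmentation <- function(object, ...) {
  g <- object$labels
  df <- tibble::tibble(row = as.vector(row(g)), col = as.vector(col(g)),
                       label = as.vector(g))
  ggplot(df, aes(.data$col, .data$row, fill = factor(.data$label))) +
    geom_raster(show.legend = FALSE) +
    coord_equal() +
    labs(title = sprintf("%d objects (well %s field %d)", object$n_objects,
                         object$well, object$field), x = NULL, y = NULL) +
    theme_minimal()
}

#' Dilution-linearity plot
#'
#' Per-well counts against 1/dilution with the least-squares line behind
#' the linearity QC.
#'
#' @param series Tibble with `dilution_factor` and `count`.
#' @return A ggplot.
#' @export
plot_dilution_linearity <- function(series) {
  ggplot(series, aes(1 / .data$dilution_factor, .data$count)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.4, colour = "grey40") +
    labs(x = "1 / dilution factor", y = "objects per imaged well",
         title = "Dilution linearity") +
    theme_minimal()
}

#' Confusion heat map of per-strain identification rates
#'
#' @param object A `strain_forest` (uses [evaluate_per_strain()] output via
#'   [tidy()]) or the long-form confusion tibble itself.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_confusion <- function(object, ...) {
  df <- if (is.data.frame(object)) object else tidy(object)
  ggplot(df, aes(.data$identified_as, .data$strain, fill = .data$rate)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f%%", 100 * .data$rate)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "identified as", y = "true strain",
         title = "Per-strain identification rates") +
    theme_minimal()
}

#' Mixture composition bar chart
#'
#' @param object A `mixture_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_report <- function(object, ...) {
  ggplot(object$composition, aes(.data$strain, .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "fraction of objects",
         title = sprintf("Mixture composition (%d objects)", object$n_objects)) +
    theme_minimal()
}
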