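# ggplot2 visualisations for the main result types.

#' Plot a per-vertex map on the unfolded rectangle
#'
#' @param mesh a [hipp_template_mesh()].
#' @param values per-vertex numeric vector.
#' @param name legend title.
#' @return a ggplot.
#' @export
plot_unfolded <- function(mesh, values, name = "value") {
  df <- tibble::tibble(ap = mesh$ap, pd = mesh$pd, value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$pd,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = name) +
    ggplot2::coord_fixed(ratio = 0.5) +
    ggplot2::labs(x = "anterior-posterior", y = "proximal-distal") +
    ggplot2::theme_minimal()
}

#' @method autoplot contrast_map
#' @export
autoplot.contrast_map <- function(object, mesh, ...) {
  plot_unfolded(mesh, object$t_age, name = "t(age)")
}

#' Age-trend panel per parcel
#'
#' Scatter of parcel-averaged values against age with per-parcel linear
#' fits, the visual counterpart of the tiered Pearson screening.
#'
#' @param data long tibble: `age`, `value`, `parcel` (optionally `sex`).
#' @param by_sex colour and fit by sex.
#' @return a ggplot.
#' @export
plot_age_trends <- function(data, by_sex = FALSE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$age, y = .data$value))
  if (by_sex && "sex" %in% names(data)) {
    p <- p + ggplot2::aes(colour = .data$sex)
  }
  p +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~parcel, scales = "free_y") +
    ggplot2::labs(x = "age (years)") +
    ggplot2::theme_minimal()
}

#' Gradient-correlation summary plot
#'
#' AP vs PD absolute correlations of age-contrast maps, point size
#' giving the mean absolute t (as in the positional-gradient analysis).
#'
#' @param gc tibble with `metric`, `r_ap`, `r_pd`, `mean_abs_t`.
#' @return a ggplot.
#' @export
plot_gradient_correlations <- function(gc) {
  ggplot2::ggplot(gc, ggplot2::aes(x = .data$r_ap, y = .data$r_pd,
                                   size = .data$mean_abs_t,
                                   label = .data$metric)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "|R| with AP gradient", y = "|R| with PD gradient",
                  size = "mean |t|") +
    ggplot2::theme_minimal()
}
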