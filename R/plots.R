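#' Plot a lactation with its fitted curves and perturbations
#'
#' Shows the daily yield, optionally the Wood curve, the expected
#' (quantile-regression) curve, and shaded perturbation episodes.
#'
#' @param series Data frame with `dim`, `dmy` for one lactation.
#' @param wood Optional `wood_fit`.
#' @param curve Optional `expected_curve`.
#' @param perturbations Optional tibble from [detect_perturbations()].
#' @return A ggplot object.
#' @export
plot_lactation <- function(series, wood = NULL, curve = NULL,
                           perturbations = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$dim, y = .data$dmy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "Days in milk", y = "Daily milk yield (kg)")
  if (!is.null(perturbations) && nrow(perturbations) > 0) {
    p <- p + ggplot2::geom_rect(
      data = perturbations,
      ggplot2::aes(xmin = .data$start_dim, xmax = .data$end_dim,
                   ymin = -Inf, ymax = Inf,
                   fill = .data$severity),
      alpha = 0.2, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(major = "firebrick",
                                            minor = "orange"))
  }
  grid <- seq(max(1, min(series$dim)), max(series$dim))
  if (!is.null(wood)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(dim = grid, dmy = wood_predict(wood, grid)),
      colour = "steelblue", linewidth = 0.7)
  }
  if (!is.null(curve)) {
    g2 <- grid[grid >= curve$window[1] & grid <= curve$window[2]]
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(dim = g2, dmy = predict(curve, g2)),
      colour = "darkgreen", linewidth = 0.7, linetype = "dashed")
  }
  p
}

#' @export
autoplot.curve_residuals <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Days in milk",
                  y = sprintf("Residual from %s curve (kg)",
                              attr(object, "model")))
}

#' @export
autoplot.resil_summary <- function(object, ...) {
  df <- dplyr::filter(object, .data$category != "Total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$term,
                                   fill = .data$percentage)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$percentage)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "Feature category", y = NULL,
                  fill = "% significant")
}
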