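#' Violin plots of per-cell counts, concentrations and spot TCCF
#'
#' Standard presentation of the study-style comparisons: violins with an
#' inset box plot (median, quartiles, whiskers at the data range).
#'
#' @param cells Per-cell tibble (`group`, `spot_count`,
#'   `concentration_per_um3`).
#' @return A ggplot object.
#' @export
plot_count_violin <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$group, y = .data$spot_count,
                                      fill = .data$group)) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.shape = NA,
                          coef = Inf) +
    ggplot2::labs(x = NULL, y = "mRNA per cell") +
    ggplot2::theme_classic()
}

#' @rdname plot_count_violin
#' @export
plot_concentration_violin <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$group,
                                      y = .data$concentration_per_um3,
                                      fill = .data$group)) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.shape = NA,
                          coef = Inf) +
    ggplot2::labs(x = NULL, y = expression(mRNA ~ per ~ mu * m^3)) +
    ggplot2::theme_classic()
}

#' @rdname plot_count_violin
#' @param spots Spot-level tibble with `group` and `tccf`.
#' @export
plot_tccf_violin <- function(spots) {
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$group, y = .data$tccf,
                                      fill = .data$group)) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.shape = NA,
                          coef = Inf) +
    ggplot2::labs(x = NULL, y = "TCCF (grey values)") +
    ggplot2::theme_classic()
}

#' Count versus volume scatter with per-group R^2
#'
#' Scatter of per-cell transcript count against estimated cell volume,
#' facetted by probe set, annotated with the Pearson R^2.
#'
#' @param cells Per-cell tibble (`group`, `spot_count`, `volume_um3`).
#' @return A ggplot object.
#' @export
plot_count_volume_scatter <- function(cells) {
  labs <- cells |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      r2 = pearson(.data$volume_um3, .data$spot_count)$r2,
      x = min(.data$volume_um3), y = max(.data$spot_count),
      .groups = "drop") |>
    dplyr::mutate(label = sprintf("R^2 == %.3f", .data$r2))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$volume_um3,
                                      y = .data$spot_count)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 0, parse = TRUE, size = 3) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = expression(cell ~ volume ~ (mu * m^3)),
                  y = "mRNA per cell") +
    ggplot2::theme_bw()
}

#' @export
autoplot.fish_quant <- function(object, ...) {
  plot_count_violin(object$cells)
}

#' @export
autoplot.study_table <- function(object, ...) {
  plot_count_violin(object$cells)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
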