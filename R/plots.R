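#' Plot a metaprofile matrix
#'
#' Mean normalized density per bin over all anchors, with the anchor at the
#' center and downstream to the right.
#'
#' @param m Matrix from [metaprofile()].
#' @param flank Half-window used to build `m` (bp), for the x axis.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(m, flank = 3000) {
  nb <- ncol(m)
  df <- tibble(
    position = seq(-flank, flank, length.out = nb + 1)[-1] - flank / nb,
    density = colMeans(m, na.rm = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from anchor (bp)",
                  y = "mean density (events per million)") +
    ggplot2::theme_minimal()
}

#' Plot a coverage-saturation curve
#'
#' @param curve Tibble from [coverage_saturation()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_used, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subsampled reads", y = "fraction of bins covered") +
    ggplot2::theme_minimal()
}

#' Plot the eRNA versus random-intergenic diversity comparison
#'
#' @param cmp Tibble from [region_diversity_compare()].
#' @param by_subgenome Facet by subgenome?
#' @return A ggplot object.
#' @export
plot_diversity_compare <- function(cmp, by_subgenome = FALSE) {
  p <- ggplot2::ggplot(cmp, ggplot2::aes(x = .data$class, y = .data$mean_pi,
                                         fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression("mean window" ~ pi)) +
    ggplot2::theme_minimal()
  if (by_subgenome) p <- p + ggplot2::facet_wrap(~subgenome)
  p
}

#' Forest-style plot of an odds-ratio result
#'
#' @param object An `or_result` from [odds_ratio()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "odds ratio", y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "odds ratio (log scale)") +
    ggplot2::theme_minimal()
}
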