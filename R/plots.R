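## ggplot2 displays for report objects.

#' Correlation heatmap
#'
#' Tile plot of the absolute Spearman correlation for every column pair
#' in the report (both triangles shown for readability; only the upper
#' triangle enters the statistics).
#'
#' @param object a `radcorr_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.radcorr_report <- function(object, ...) {
  pairs <- object$pairs
  both <- dplyr::bind_rows(
    dplyr::select(pairs, a = "col_a", b = "col_b", "abs_rho"),
    dplyr::select(pairs, a = "col_b", b = "col_a", "abs_rho"))
  lev <- sort(unique(c(pairs$col_a, pairs$col_b)))
  both$a <- factor(both$a, levels = lev)
  both$b <- factor(both$b, levels = lev)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$abs_rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|rho|") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Absolute Spearman correlation") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Histograms of significant correlations by comparison class
#'
#' @param object a `radcorr_summary`.
#' @param ... unused.
#' @return a ggplot faceted by comparison class and group.
#' @export
autoplot.radcorr_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.9) +
    ggplot2::facet_grid(class ~ group) +
    ggplot2::labs(x = "|rho| (significant pairs)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Correlation power curves
#'
#' Power of the zero-correlation test as a function of sample size for
#' one or more effect sizes.
#'
#' @param rho effect sizes (vector).
#' @param n_range integer range of sample sizes.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return a ggplot.
#' @export
plot_power_curve <- function(rho = c(0.3, 0.5, 0.75),
                             n_range = seq(5, 150, by = 5),
                             alpha = 0.05, tails = 2) {
  grid <- tidyr::expand_grid(rho = rho, n = n_range)
  grid$power <- purrr::map2_dbl(grid$n, grid$rho,
                                ~power_correlation(.x, .y, alpha, tails))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n, y = .data$power,
                                     colour = factor(.data$rho))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "effect size", x = "sample size",
                  y = "power") +
    ggplot2::theme_minimal()
}
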