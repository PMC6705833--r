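#' Plot an S-H-ESD fit
#'
#' Daily totals on a log vertical axis (large spikes would otherwise crush
#' the body of the series), the fitted expectation (seasonal + trend), and
#' the flagged outlying days highlighted.
#'
#' @param object An `shesd` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shesd <- function(object, ...) {
  dec <- object$decomposition
  ggplot2::ggplot(dec, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.3,
                       colour = "grey30") +
    ggplot2::geom_step(ggplot2::aes(y = .data$trend), colour = "black",
                       linewidth = 0.6) +
    ggplot2::geom_point(data = object$outliers,
                        ggplot2::aes(y = .data$observed),
                        colour = "#D55E00", size = 1.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Daily pageviews (log scale)",
                  title = "Daily pageview totals with outlying days",
                  subtitle = paste0(nrow(object$outliers),
                                    " flagged day(s); step line = piecewise-median trend")) +
    ggplot2::theme_minimal()
}

#' Plot a robust decomposition
#'
#' One facet per component (observed, seasonal, trend, remainder), sharing
#' the date axis.
#'
#' @param object An `shesd_decomposition` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shesd_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("observed", "seasonal", "trend", "remainder"),
                              names_to = "component", values_to = "value") |>
    dplyr::mutate(component = factor(.data$component,
                                     c("observed", "seasonal", "trend", "remainder")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Robust additive decomposition") +
    ggplot2::theme_minimal()
}

#' Plot a language share table
#'
#' Horizontal bars of per-language share of total pageviews, the rollup
#' bucket last.
#'
#' @param shares A tibble from [language_shares()].
#' @return A ggplot object.
#' @export
plot_language_shares <- function(shares) {
  shares <- dplyr::mutate(shares,
                          language = factor(.data$language, rev(.data$language)))
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$share, y = .data$language)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Share of pageviews", y = NULL,
                  title = "Pageviews by language localization") +
    ggplot2::theme_minimal()
}
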