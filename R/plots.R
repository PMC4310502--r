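#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a demeaned-AR(1) bias curve
#'
#' Bias against series length T, one line per autoregressive parameter.
#'
#' @param object A [bias_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(bias_curve())
#' @export
autoplot.inertia_bias_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$T, y = .data$bias,
                               colour = factor(.data$phi),
                               group = factor(.data$phi))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Occasions per cluster (T)",
                  y = "Bias of demeaned AR(1) slope",
                  colour = expression(phi)) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo summary
#'
#' Bias (with ±2 Monte-Carlo SE bars) per estimator/centering scheme.
#'
#' @param object An `inertia_mc` summary from [run_condition()] or
#'   [run_table()].
#' @param parameter Which parameter to show (default `"gamma10"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inertia_mc <- function(object, parameter = "gamma10", ...) {
  dat <- dplyr::filter(tibble::as_tibble(object),
                       .data$param == parameter)
  dat$label <- ifelse(is.na(dat$scheme), dat$estimator,
                      paste(dat$estimator, dat$scheme))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$bias - 2 * .data$mc_se,
                   ymax = .data$bias + 2 * .data$mc_se)) +
    ggplot2::labs(x = NULL, y = paste("Bias of", parameter)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Spaghetti plot of a simulated panel
#'
#' @param panel A panel tibble.
#' @param max_clusters Draw at most this many clusters.
#' @return A ggplot.
#' @export
plot_panel <- function(panel, max_clusters = 20) {
  keep <- utils::head(sort(unique(panel$cluster)), max_clusters)
  dat <- dplyr::filter(panel, .data$cluster %in% keep)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$y,
                                    group = .data$cluster)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Occasion", y = "y") +
    ggplot2::theme_minimal()
}
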