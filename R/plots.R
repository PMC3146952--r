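#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power curve
#'
#' One line per tested term, with pointwise Monte-Carlo error bars
#' (plus/minus one MC SE). If the curve carries an analytic benchmark
#' column it is drawn as a dashed line.
#'
#' @param object A `power_curve` from [power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$clusters_per_arm,
                                            y = .data$power,
                                            colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$power - .data$mc_se,
                                          ymax = .data$power + .data$mc_se),
                             size = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "clusters per arm", y = "power (1 - Type II error)",
                  colour = "term") +
    ggplot2::theme_minimal()
  if ("analytic" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$analytic),
                                linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a null-calibration report
#'
#' The QQ panel plots sorted null p-values against uniform plotting
#' positions `(k - 0.5) / R`; a calibrated simulation falls on the line of
#' equality. `type = "hist"` draws the p-value histogram instead, which
#' should be flat.
#'
#' @param object A `calibration_report` from [null_calibration()].
#' @param type `"qq"` (default) or `"hist"`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, type = c("qq", "hist"),
                                        bins = 20, ...) {
  type <- match.arg(type)
  if (type == "qq") {
    ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$uniform,
                                            y = .data$pvalue)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
      ggplot2::geom_point(size = 0.4, alpha = 0.5) +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "uniform quantile", y = "observed p-value quantile",
                    title = "Null p-value QQ plot") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$pvalue)) +
      ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey60",
                              colour = "white") +
      ggplot2::labs(x = "p-value", y = "count",
                    title = "Null p-value histogram") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
NULL
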