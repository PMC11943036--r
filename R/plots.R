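#' Plot cumulative-incidence curves
#'
#' Step-style cumulative-incidence curves by strategy, with optional
#' confidence ribbons when `lo`/`hi` columns are present.
#'
#' @param curves Tibble `(strategy, day, cum_inc[, lo, hi])`.
#' @return A ggplot.
#' @export
plot_risk_curves <- function(curves) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$day, y = .data$cum_inc,
                                    colour = .data$strategy,
                                    fill = .data$strategy))
  if (all(c("lo", "hi") %in% names(curves))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  alpha = 0.2, colour = NA)
  }
  p +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Days since referral",
                  y = "Cumulative incidence of extubation",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-day risk differences
#'
#' @param rd Tibble `(strategy, day, rd[, lo, hi])` from an effect report.
#' @param ref Reference strategy name for the axis label.
#' @return A ggplot.
#' @export
plot_risk_difference <- function(rd, ref = NULL) {
  ylab <- if (is.null(ref)) "Cumulative incidence difference" else
    sprintf("Cumulative incidence difference (ref. %s)", ref)
  p <- ggplot2::ggplot(rd, ggplot2::aes(x = .data$day, y = .data$rd,
                                        group = .data$strategy))
  if (all(c("lo", "hi") %in% names(rd))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  alpha = 0.2)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f pp", 100 * x)) +
    ggplot2::labs(x = "Days since referral", y = ylab) +
    ggplot2::theme_minimal()
}

#' Two-panel emulation figure
#'
#' Panel A: cumulative incidence by strategy; panel B: per-day risk
#' difference against the reference strategy. For a `ccw_boot`, percentile
#' ribbons are drawn on both panels.
#'
#' @param object A `ccw_fit` or `ccw_boot`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @export
autoplot.ccw_fit <- function(object, ...) {
  patchwork::wrap_plots(
    plot_risk_curves(object$curves),
    plot_risk_difference(object$effects$rd, ref = object$effects$ref),
    ncol = 2
  ) + patchwork::plot_annotation(tag_levels = "A")
}

#' @rdname autoplot.ccw_fit
#' @export
autoplot.ccw_boot <- function(object, ...) {
  patchwork::wrap_plots(
    plot_risk_curves(object$curve_bands),
    plot_risk_difference(object$rd_bands, ref = object$fit$effects$ref),
    ncol = 2
  ) + patchwork::plot_annotation(tag_levels = "A")
}
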