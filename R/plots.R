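# ggplot2 visualisations of the result types.

#' Plot state occupancy over time
#'
#' Stacked area chart of the cohort fraction in each state per cycle.
#'
#' @param object A `lvad_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvad_trace
#' @export
autoplot.lvad_trace <- function(object, ...) {
  states <- attr(object, "states")
  long <- tidyr::pivot_longer(as_tibble.lvad_trace(object),
                              cols = dplyr::all_of(states),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = states)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "cycle (months)", y = "cohort fraction",
                  title = sprintf("%s arm state occupancy", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `lvad_ceac` from [compute_ceac()].
#' @param thresholds Willingness-to-pay values to mark with vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvad_ceac
#' @export
autoplot.lvad_ceac <- function(object, thresholds = c(20000, 30000, 50000), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "willingness to pay (GBP per QALY)",
                  y = "probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the ICER at each parameter's low value to the ICER
#' at its high value, widest on top.
#'
#' @param object A `lvad_tornado` from [run_owsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvad_tornado
#' @export
autoplot.lvad_tornado <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base_icer <- mean(c(df$icer_low[df$width == 0], NA), na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "ICER (GBP per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (is.finite(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed")
  }
  p
}

#' Plot the cost-effectiveness plane from PSA draws
#'
#' Incremental cost against incremental QALYs, one point per draw, with
#' willingness-to-pay reference lines through the origin.
#'
#' @param object A `lvad_psa` from [run_psa()].
#' @param wtp Willingness-to-pay slopes to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lvad_psa
#' @export
autoplot.lvad_psa <- function(object, wtp = c(30000, 50000), ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$inc_qaly, y = .data$inc_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "incremental QALYs", y = "incremental cost (GBP)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
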