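#' Cost-effectiveness plane
#'
#' Scatter of the per-iteration incremental (QALY, cost) pairs with the
#' willingness-to-pay threshold line and the iteration mean.
#'
#' @param psa A `psa_result`.
#' @return A `ggplot` object.
#' @export
plot_ce_plane <- function(psa) {
  df <- psa$draws
  ggplot2::ggplot(df, ggplot2::aes(x = de, y = dc)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::annotate("point", x = mean(df$de), y = mean(df$dc),
                      colour = "red", size = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental costs (EUR)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("WTP threshold EUR %s/QALY (dashed)",
                                     format(psa$wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @return A `ggplot` object.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = wtp, y = prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = psa$wtp, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the iNMB at each parameter's low and high value,
#' widest on top, with a vertical reference at the base-case iNMB.
#'
#' @param tornado Result of [run_owsa()].
#' @return A `ggplot` object.
#' @export
plot_tornado <- function(tornado) {
  df <- as.data.frame(tornado)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(tornado, "base_inmb")
  ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = inmb_lo, xend = inmb_hi,
                                       yend = parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Incremental net monetary benefit (EUR)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
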