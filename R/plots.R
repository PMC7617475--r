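# ggplot2 visualisations of the main result types.

#' Plot cluster mean trajectories with confidence ribbons
#'
#' @param object A [cluster_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot object: mean scaled expression over time per cluster,
#'   95% CI ribbon, half-time marked where defined.
#' @export
autoplot.kinetic_clusters <- function(object, ...) {
  tr <- object$trajectories
  halves <- object$clusters %>% filter(.data$retained, !is.na(.data$t_half))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$timepoint,
                                   y = .data$mean_scaled)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    ) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_vline(
      data = halves, ggplot2::aes(xintercept = .data$t_half),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "time after induction (h)",
                  y = "scaled normalized expression")
}

#' Plot a signal metaprofile
#'
#' @param object A [metaprofile()] result.
#' @param ... Unused.
#' @return A ggplot object of mean signal against offset from the centre.
#' @export
autoplot.metaprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from centre (bp)", y = "mean signal")
}

#' Plot the super-enhancer rank-signal curve
#'
#' @param object A [call_super_enhancers()] result.
#' @param ... Unused.
#' @return A ggplot object: the hockey-stick curve with super-enhancers
#'   highlighted.
#' @export
autoplot.se_call <- function(object, ...) {
  ggplot2::ggplot(object$regions,
                  ggplot2::aes(x = .data$rank, y = .data$total_signal,
                               colour = .data$is_super)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "rank", y = "total signal",
                  colour = "super-enhancer")
}

#' Plot burst fractions for two conditions
#'
#' @param object A [compare_conditions()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of burst fractions, annotated with the
#'   Fisher p-value.
#' @export
autoplot.burst_comparison <- function(object, ...) {
  df <- tibble(
    condition = c("condition0", "condition1"),
    fraction = c(object$fraction0, object$fraction1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      y = "burst fraction",
      subtitle = sprintf("Fisher p = %.3g; modulation: %s",
                         object$fisher_p, object$modulation)
    )
}
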