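#' Bar chart of phase-level percentages
#'
#' Grouped bars of one phase metric (activity, interaction or movement
#' percentage) per clinical phase, split by surgery type — the shape of the
#' published activity/interaction summaries.
#'
#' @param metrics Per-procedure [phase_metrics()] rows or a
#'   [summarize_phase_metrics()] table.
#' @param metric Which percentage to plot.
#' @return A ggplot object.
#' @export
plot_phase_metrics <- function(metrics,
                               metric = c("activity_pct", "interaction_pct",
                                          "movement_pct")) {
  metric <- match.arg(metric)
  assert_columns(metrics, c("surgery_type", "phase", metric), "metrics")
  df <- metrics %>%
    group_by(.data$surgery_type, .data$phase) %>%
    summarise(value = mean(.data[[metric]], na.rm = TRUE), .groups = "drop") %>%
    mutate(phase = factor(.data$phase, levels = 1:3,
                          labels = paste("Phase", 1:3)))
  lab <- c(activity_pct = "Activity (% of mean phase duration)",
           interaction_pct = "Interaction at table (%)",
           movement_pct = "Movement (%)")[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$value,
                                   fill = .data$surgery_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = lab, fill = "Surgery type") +
    ggplot2::theme_minimal()
}

#' Boxplots of summed instrument scores
#'
#' Per-domain boxplots of phase-summed scores by surgery type (or
#' type-summed scores by phase), the shape of the published score
#' comparisons.
#'
#' @param x A `surgtlx_analysis` object.
#' @param comparison `"surgery_type"` or `"phase"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surgtlx_analysis <- function(x, comparison = c("surgery_type", "phase"),
                                      ...) {
  comparison <- match.arg(comparison)
  sums <- purrr::map(surgtlx_domains(), function(dom) {
    sum_scores(x$responses, dom, comparison) %>% mutate(domain = dom)
  }) %>% bind_rows()
  sums[[comparison]] <- factor(sums[[comparison]])
  ggplot2::ggplot(sums, ggplot2::aes(x = .data[[comparison]], y = .data$score,
                                     fill = .data[[comparison]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~domain, nrow = 2) +
    ggplot2::labs(
      x = NULL,
      y = if (comparison == "surgery_type") {
        "Score summed over phases (0-60)"
      } else {
        "Score summed over surgery types (0-60)"
      }
    ) +
    ggplot2::theme_minimal()
}
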