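# ggplot2 visualizations for traces, rankings and counterfactuals.

#' Plot one participant-day CGM trace with its postprandial window
#'
#' Shades the postprandial window after the meal and marks the
#' hyperglycemia threshold.
#'
#' @param trace Single-participant tibble with `timestamp`, `glucose`.
#' @param date Day to plot.
#' @param meal_time Optional `hms` lunch time to annotate.
#' @param horizon_h Postprandial horizon, hours.
#' @param threshold Hyperglycemia threshold, mg/dL.
#' @return A ggplot object.
#' @export
plot_cgm_day <- function(trace, date, meal_time = NULL, horizon_h = 3,
                         threshold = 140) {
  day <- trace_day(trace, date)
  p <- ggplot2::ggplot(day,
                       ggplot2::aes(x = .data$timestamp,
                                    y = .data$glucose)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = NULL, y = "glucose (mg/dL)",
                  title = sprintf("CGM trace, %s", format(as.Date(date))))
  if (!is.null(meal_time)) {
    m0 <- at_clock(date, hms::as_hms(meal_time))
    p <- p + ggplot2::annotate("rect", xmin = m0,
                               xmax = m0 + horizon_h * 3600,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "orange") +
      ggplot2::geom_vline(xintercept = m0, linetype = "dotted")
  }
  p
}

#' @export
autoplot.counterfactual_set <- function(object, ...) {
  ch <- tidy(object)
  if (nrow(ch) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "no counterfactuals found"))
  }
  long <- ch %>%
    tidyr::pivot_longer(c("original", "counterfactual"),
                        names_to = "which", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$value, y = .data$feature,
                               colour = .data$which)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$feature),
                       colour = "grey50",
                       arrow = ggplot2::arrow(length =
                                                ggplot2::unit(4, "pt"))) +
    ggplot2::facet_wrap(~cf, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "feature value", y = NULL, colour = NULL,
                  title = sprintf("Treatment pathways: class %d → %d",
                                  object$query_class, object$target_class))
}

#' Plot a Shapley feature ranking
#'
#' @param ranking Output of [shap_rank()].
#' @param top_n Features to display.
#' @return A ggplot object.
#' @export
plot_shap_rank <- function(ranking, top_n = 15) {
  top <- ranking %>% dplyr::slice_head(n = top_n)
  ggplot2::ggplot(top,
                  ggplot2::aes(x = .data$importance,
                               y = stats::reorder(.data$feature,
                                                  .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley contribution|", y = NULL)
}

#' Plot tolerance fractions of a regression evaluation
#'
#' @param y_true,y_pred Numeric vectors.
#' @param thresholds Relative-error thresholds (fractions).
#' @return A ggplot object.
#' @export
plot_tolerance <- function(y_true, y_pred,
                           thresholds = c(0.05, 0.1, 0.15, 0.2)) {
  fr <- tolerance_fractions(y_true, y_pred, thresholds)
  df <- tibble(threshold = thresholds * 100, fraction = as.numeric(fr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "error tolerance (%)", y = "fraction of test cases")
}
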