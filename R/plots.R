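#' Plot per-fold evaluation metrics
#'
#' Boxplot of the fold-level metrics of a leave-one-patient-out run.
#'
#' @param object a `lopo_eval`.
#' @param metrics metric columns to show.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lopo_eval <- function(object,
                               metrics = c("auroc", "sensitivity",
                                           "event_recall", "false_alarm_rate"),
                               ...) {
  long <- object$folds %>%
    select("fold", all_of(metrics)) %>%
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "fold-level value",
                  title = "Leave-one-patient-out evaluation") +
    ggplot2::theme_minimal()
}

#' Bar chart of global feature importance
#'
#' @param report tibble from [global_report()].
#' @return A ggplot.
#' @export
plot_importance <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$importance,
                               y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean mask importance", y = NULL,
                  title = "Top decision-mask features") +
    ggplot2::theme_minimal()
}

#' Heatmap of mask importance over lookback hours
#'
#' @param heat tibble from [temporal_heatmap_data()].
#' @return A ggplot.
#' @export
plot_temporal_heatmap <- function(heat) {
  ggplot2::ggplot(heat,
                  ggplot2::aes(x = .data$hour, y = .data$channel,
                               fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "lookback hour", y = NULL,
                  title = "Mask importance across the lookback window") +
    ggplot2::theme_minimal()
}

#' Replay one stay's alarm trace
#'
#' Hourly predicted probability with the alarm threshold and any arrest
#' onsets marked.
#'
#' @param lopo a `lopo_eval`.
#' @param cohort cohort tibble.
#' @param stay_id the stay to plot.
#' @return A ggplot.
#' @export
plot_stay <- function(lopo, cohort, stay_id) {
  preds <- lopo$predictions %>% filter(.data$stay_id == !!stay_id)
  if (!nrow(preds)) abort(paste0("no predictions for stay ", stay_id))
  ev <- cohort$ca_event_hours[[match(stay_id, cohort$stay_id)]]
  p <- ggplot2::ggplot(preds, ggplot2::aes(x = .data$t_end, y = .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = lopo$config$threshold, linetype = 2) +
    ggplot2::labs(x = "hours since admission", y = "arrest risk",
                  title = paste("Pseudo-real-time replay:", stay_id)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (length(ev)) {
    p <- p + ggplot2::geom_vline(xintercept = ev, colour = "red")
  }
  p
}
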