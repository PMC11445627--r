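#' Area under the ROC curve (rank statistic)
#'
#' Midrank (Mann-Whitney) AUROC; `NA` when only one class is present.
#'
#' @param prob predicted probabilities; @param y binary labels.
#' @return AUROC in `[0, 1]`, or `NA`.
#' @export
auroc <- function(prob, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Event-based alarm metrics for a prediction series
#'
#' Replays hourly predictions against the recorded arrest onsets. An alarm is
#' a prediction at or above `threshold`; it is *true* when an arrest follows
#' within the horizon (equivalently, its window label is 1). An event is
#' *captured* when at least one true alarm fires in its pre-onset span
#' (`t_end` in `[onset - horizon, onset)`). Event recall is
#' `N_captured / N_total`; the false alarm rate is `1 - N_true / N_alarm`,
#' reported as `NA` when no alarm fired (the ratio is undefined). Sample
#' sensitivity/specificity, the Brier score and pooled AUROC come from the
#' (probability, label) pairs.
#'
#' @param predictions tibble with `stay_id`, `t_end`, `prob`, `label`.
#' @param cohort cohort tibble supplying `ca_event_hours` per stay.
#' @param threshold alarm operating point (default 0.5).
#' @param horizon_hours alarm horizon (default 24).
#' @return A one-row tibble: `auroc`, `sensitivity`, `specificity`,
#'   `event_recall`, `false_alarm_rate`, `brier`, `n_windows`, `n_alarm`,
#'   `n_true`, `n_events`, `n_captured`.
#' @export
event_metrics <- function(predictions, cohort, threshold = 0.5,
                          horizon_hours = 24) {
  stopifnot(all(c("stay_id", "t_end", "prob", "label") %in% names(predictions)))
  alarm <- predictions$prob >= threshold
  label <- as.integer(predictions$label)
  n_alarm <- sum(alarm)
  n_true <- sum(alarm & label == 1)
  stays <- cohort[cohort$stay_id %in% unique(predictions$stay_id), ]
  n_events <- 0L
  n_captured <- 0L
  pred_split <- split(predictions[alarm & label == 1, c("stay_id", "t_end")],
                      predictions$stay_id[alarm & label == 1])
  for (i in seq_len(nrow(stays))) {
    ev <- stays$ca_event_hours[[i]]
    if (!length(ev)) next
    n_events <- n_events + length(ev)
    ta <- pred_split[[stays$stay_id[i]]]
    if (is.null(ta) || !nrow(ta)) next
    for (e in ev) {
      if (any(ta$t_end < e & e <= ta$t_end + horizon_hours)) {
        n_captured <- n_captured + 1L
      }
    }
  }
  tibble(
    auroc = auroc(predictions$prob, label),
    sensitivity = if (sum(label == 1)) n_true / sum(label == 1) else NA_real_,
    specificity = if (sum(label == 0)) sum(!alarm & label == 0) / sum(label == 0) else NA_real_,
    event_recall = if (n_events) n_captured / n_events else NA_real_,
    false_alarm_rate = if (n_alarm) 1 - n_true / n_alarm else NA_real_,
    brier = mean((predictions$prob - label)^2),
    n_windows = nrow(predictions),
    n_alarm = n_alarm, n_true = n_true,
    n_events = n_events, n_captured = n_captured
  )
}
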