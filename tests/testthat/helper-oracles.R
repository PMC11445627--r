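# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (double loops, exhaustive enumeration) and share no code
# with the implementation they check.

oracle_gini <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + abs(x[i] - x[j])
  acc / (2 * n^2 * mean(x))
}

oracle_label_windows <- function(los_hours, events, W = 12, horizon = 24,
                                 gap = 24) {
  out <- list()
  for (t_end in seq_len(floor(los_hours))) {
    if (t_end < W) next
    blocked <- FALSE
    for (e in events) if (e <= t_end && t_end < e + gap) blocked <- TRUE
    if (blocked) next
    label <- 0L
    for (e in events) if (t_end < e && e <= t_end + horizon) label <- 1L
    out[[length(out) + 1]] <- data.frame(t_end = t_end, label = label)
  }
  if (!length(out)) {
    return(data.frame(t_end = integer(0), label = integer(0)))
  }
  do.call(rbind, out)
}

# hour-by-hour replay over every prediction and every event; plain vectors
# are hoisted out of the loops so the brute force stays affordable
oracle_event_metrics <- function(preds, events_by_stay, tau, horizon = 24) {
  prob <- preds$prob; lab <- preds$label
  stay <- preds$stay_id; t_end <- preds$t_end
  n_alarm <- 0L; n_true <- 0L; tp <- 0L; fn <- 0L; tn <- 0L; fp <- 0L
  for (i in seq_along(prob)) {
    alarm <- prob[i] >= tau
    if (alarm) {
      n_alarm <- n_alarm + 1L
      if (lab[i] == 1) n_true <- n_true + 1L
    }
    if (lab[i] == 1 && alarm) tp <- tp + 1L
    if (lab[i] == 1 && !alarm) fn <- fn + 1L
    if (lab[i] == 0 && !alarm) tn <- tn + 1L
    if (lab[i] == 0 && alarm) fp <- fp + 1L
  }
  n_events <- 0L; n_captured <- 0L
  for (sid in names(events_by_stay)) {
    for (e in events_by_stay[[sid]]) {
      n_events <- n_events + 1L
      captured <- FALSE
      for (i in which(stay == sid)) {
        if (prob[i] >= tau && lab[i] == 1 &&
            t_end[i] < e && e <= t_end[i] + horizon) {
          captured <- TRUE
        }
      }
      if (captured) n_captured <- n_captured + 1L
    }
  }
  list(
    sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    event_recall = if (n_events) n_captured / n_events else NA_real_,
    false_alarm_rate = if (n_alarm) 1 - n_true / n_alarm else NA_real_,
    brier = mean((preds$prob - preds$label)^2),
    n_alarm = n_alarm, n_true = n_true,
    n_events = n_events, n_captured = n_captured
  )
}

# random small prediction series with events, for metric equivalence checks
random_eval_instance <- function(seed) {
  withr::with_seed(seed, {
    n_stays <- sample(3:20, 1)
    cohort <- tibble::tibble(
      stay_id = sprintf("S%02d", seq_len(n_stays)),
      patient_id = sprintf("P%02d", seq_len(n_stays)),
      age_years = runif(n_stays, 30, 90),
      icu_subtype = sample(c("general", "cardiac"), n_stays, TRUE),
      los_hours = runif(n_stays, 14, 100),
      ca_event_hours = lapply(seq_len(n_stays), function(i) numeric(0))
    )
    preds <- list()
    for (i in seq_len(n_stays)) {
      los <- cohort$los_hours[i]
      if (runif(1) < 0.4) {
        n_ev <- sample(1:2, 1)
        ev <- sort(runif(n_ev, 13, los))
        ev <- ev[c(TRUE, diff(ev) > 30)]
        cohort$ca_event_hours[[i]] <- round(ev, 1)
      }
      w <- oracle_label_windows(los, cohort$ca_event_hours[[i]])
      if (!nrow(w)) next
      preds[[length(preds) + 1]] <- tibble::tibble(
        stay_id = cohort$stay_id[i], t_end = w$t_end, label = w$label,
        prob = round(runif(nrow(w)), 3)
      )
    }
    list(cohort = cohort, predictions = dplyr::bind_rows(preds))
  })
}

# keep the index columns plus a deterministic subset of feature columns;
# harness-mechanics tests do not need the full 637-feature design
slim_features <- function(fm, n_keep = 60) {
  meta <- intersect(c("stay_id", "patient_id", "t_end", "label"), names(fm))
  feats <- setdiff(names(fm), meta)
  fm[, c(meta, feats[seq_len(min(n_keep, length(feats)))])]
}
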