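#' Apply cohort inclusion criteria
#'
#' Keeps stays of adults (age strictly over `min_age` and strictly under
#' `max_age`) long enough to carry at least one labeled lookback window
#' (`los_hours >= window_hours + 1`). With `strict_event_timing = TRUE`, arrest
#' stays must additionally have at least one vital observation in the hour
#' before each onset. Every exclusion is recorded with a reason code in the
#' `"exclusions"` attribute.
#'
#' @param cohort cohort tibble.
#' @param config an [arrest_config()].
#' @param obs observation tibble; only needed for strict event timing.
#' @return The filtered cohort; `attr(., "exclusions")` is a tibble
#'   `stay_id`, `reason`.
#' @export
apply_inclusion <- function(cohort, config = arrest_config(), obs = NULL) {
  config <- as_arrest_config(config)
  reason <- rep(NA_character_, nrow(cohort))
  too_young <- cohort$age_years <= config$min_age
  too_old <- cohort$age_years >= config$max_age
  too_short <- cohort$los_hours < config$window_hours + 1
  reason[too_short] <- "too_short"
  reason[too_old] <- "age_out_of_range"
  reason[too_young] <- "age_out_of_range"
  if (isTRUE(config$strict_event_timing)) {
    if (is.null(obs)) abort("strict_event_timing requires the observation table")
    for (i in which(is.na(reason) & lengths(cohort$ca_event_hours) > 0)) {
      ev <- cohort$ca_event_hours[[i]]
      t_h <- obs$t_min[obs$stay_id == cohort$stay_id[i]] / 60
      ok <- vapply(ev, function(e) any(t_h >= e - 1 & t_h < e), logical(1))
      if (!all(ok)) reason[i] <- "no_observation_before_onset"
    }
  }
  excl <- tibble(stay_id = cohort$stay_id[!is.na(reason)],
                 reason = reason[!is.na(reason)])
  if (isTRUE(getOption("arrestwatch.verbose")) && nrow(excl)) {
    inform(paste0("apply_inclusion: excluded ", nrow(excl), " stay(s)"))
  }
  out <- cohort[is.na(reason), ]
  attr(out, "exclusions") <- excl
  out
}

#' Enumerate labeled lookback windows for each stay
#'
#' One window per whole hour `t_end` from `window_hours` to `floor(los_hours)`;
#' the window looks back over hours `[t_end - window_hours, t_end)` and its
#' label is 1 iff some arrest onset `e` satisfies
#' `t_end < e <= t_end + horizon_hours` (half-open horizon). Windows whose
#' lookback would cross an earlier arrest — or that fall within
#' `resume_gap_hours` after one — are dropped, excluding post-arrest
#' physiology; emission resumes once the gap has passed, so multi-event stays
#' are replayed between events.
#'
#' @param cohort cohort tibble (already through [apply_inclusion()]).
#' @param config an [arrest_config()].
#' @return A tibble `stay_id`, `t_end`, `label` (integer 0/1).
#' @export
label_windows <- function(cohort, config = arrest_config()) {
  config <- as_arrest_config(config)
  W <- config$window_hours
  Hz <- config$horizon_hours
  gap <- config$resume_gap_hours
  out <- purrr::map(seq_len(nrow(cohort)), function(i) {
    n_hours <- floor(cohort$los_hours[i])
    if (n_hours < W) return(NULL)
    t_end <- seq.int(W, n_hours)
    ev <- cohort$ca_event_hours[[i]]
    if (length(ev)) {
      blocked <- vapply(t_end, function(t) any(ev <= t & t < ev + gap), logical(1))
      t_end <- t_end[!blocked]
      if (!length(t_end)) return(NULL)
      label <- as.integer(vapply(t_end, function(t) any(t < ev & ev <= t + Hz),
                                 logical(1)))
    } else {
      label <- integer(length(t_end))
    }
    tibble(stay_id = cohort$stay_id[i], t_end = as.integer(t_end), label = label)
  })
  empty <- tibble(stay_id = character(0), t_end = integer(0), label = integer(0))
  bind_rows(c(list(empty), out))
}
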