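#' Remove physiologically implausible observations
#'
#' Drops every observation falling outside its signal's plausibility range
#' (bounds inclusive). The per-signal removal counts are attached as the
#' `"removed"` attribute and reported when `options(arrestwatch.verbose = TRUE)`.
#'
#' @param obs observation tibble (`stay_id`, `signal`, `t_min`, `value`).
#' @param ranges per-signal bounds, see [default_ranges()].
#' @return The filtered observation tibble.
#' @export
remove_outliers <- function(obs, ranges = default_ranges()) {
  check_ranges(ranges, unique(obs$signal))
  m <- match(obs$signal, ranges$signal)
  keep <- obs$value >= ranges$low[m] & obs$value <= ranges$high[m]
  removed <- obs[!keep, ] %>% count(.data$signal, name = "n_removed")
  if (isTRUE(getOption("arrestwatch.verbose")) && nrow(removed)) {
    inform(paste0("remove_outliers: dropped ", sum(removed$n_removed), " row(s)"))
  }
  out <- obs[keep, ]
  attr(out, "removed") <- removed
  out
}

#' Bucket irregular observations onto an hourly grid
#'
#' Hour bucket `h` (0-based) covers minutes `[60h, 60(h+1))`; the values inside
#' a bucket are averaged (duplicates at one timestamp included). Buckets with
#' no observation carry `NA` and `missing = TRUE`. The grid spans every whole
#' hour of each stay (`floor(los_hours)` buckets) and every signal in
#' `signals`, so downstream stages see a dense signal-by-hour layout.
#'
#' @param obs outlier-filtered observation tibble.
#' @param cohort cohort tibble supplying `los_hours` per stay.
#' @param signals signals to grid (default all six vitals).
#' @return A long tibble `stay_id`, `signal`, `hour`, `value`, `missing`.
#' @export
bucket_hourly <- function(obs, cohort, signals = vital_signals()) {
  if (any(floor(cohort$los_hours) < 1)) {
    abort(paste0("stay(s) shorter than one hour cannot be gridded: ",
                 paste(cohort$stay_id[floor(cohort$los_hours) < 1], collapse = ", ")))
  }
  frame <- cohort %>%
    mutate(n_hours = as.integer(floor(.data$los_hours))) %>%
    select("stay_id", "n_hours")
  skeleton <- frame %>%
    dplyr::reframe(hour = seq_len(.data$n_hours) - 1L, .by = "stay_id") %>%
    tidyr::expand_grid(signal = signals) %>%
    select("stay_id", "signal", "hour")
  means <- obs %>%
    inner_join(frame, by = "stay_id") %>%
    mutate(hour = .data$t_min %/% 60L) %>%
    filter(.data$hour < .data$n_hours, .data$signal %in% signals) %>%
    summarise(value = mean(.data$value), .by = c("stay_id", "signal", "hour"))
  skeleton %>%
    left_join(means, by = c("stay_id", "signal", "hour")) %>%
    mutate(missing = is.na(.data$value)) %>%
    arrange(.data$stay_id, .data$signal, .data$hour)
}

#' Impute missing hourly buckets by carrying observations
#'
#' Within each stay-signal series, every missing bucket first takes the nearest
#' *later* observed value (last observation carried backward); a trailing run
#' of missing buckets then takes the nearest *earlier* observed value (carried
#' forward). Series with zero observations are left missing and flagged in the
#' `"fully_missing"` attribute; they are filled at the normalization stage.
#' The `missing` mask is preserved so imputed buckets remain identifiable.
#' The rule uses only within-stay information, so imputing arrest and
#' non-arrest stays together or separately gives identical results.
#'
#' @param grid hourly grid from [bucket_hourly()].
#' @return The grid with `value` imputed; idempotent.
#' @export
impute_grid <- function(grid) {
  out <- grid %>%
    group_by(.data$stay_id, .data$signal) %>%
    mutate(value = {
      v <- zoo::na.locf(.data$value, fromLast = TRUE, na.rm = FALSE)
      zoo::na.locf(v, na.rm = FALSE)
    }) %>%
    ungroup()
  fully <- out %>%
    summarise(all_missing = all(is.na(.data$value)),
              .by = c("stay_id", "signal")) %>%
    filter(.data$all_missing) %>%
    select("stay_id", "signal")
  if (isTRUE(getOption("arrestwatch.verbose")) && nrow(fully)) {
    inform(paste0("impute_grid: ", nrow(fully),
                  " fully unobserved stay-signal series left for fill"))
  }
  attr(out, "fully_missing") <- fully
  out
}

#' Min-max normalize an imputed hourly grid
#'
#' Maps each value to `(value - low) / (high - low)` using the per-signal
#' normalization bounds; because outliers were removed against the same
#' bounds, outputs lie in `[0, 1]`. Buckets still missing after imputation
#' (fully unobserved series) are filled with `fill_value`, the normalized
#' cohort midpoint.
#'
#' @param grid imputed hourly grid.
#' @param spec normalization bounds (`signal`, `low`, `high`).
#' @param fill_value normalized value for fully unobserved series.
#' @return The grid with `value` on the normalized scale.
#' @export
normalize_grid <- function(grid, spec = default_ranges(), fill_value = 0.5) {
  check_ranges(spec, unique(grid$signal))
  m <- match(grid$signal, spec$signal)
  out <- grid
  out$value <- (grid$value - spec$low[m]) / (spec$high[m] - spec$low[m])
  out$value[is.na(out$value)] <- fill_value
  out
}

#' Invert min-max normalization
#' @rdname normalize_grid
#' @export
denormalize_grid <- function(grid, spec = default_ranges()) {
  check_ranges(spec, unique(grid$signal))
  m <- match(grid$signal, spec$signal)
  out <- grid
  out$value <- grid$value * (spec$high[m] - spec$low[m]) + spec$low[m]
  out
}

#' Run the full preprocessing chain
#'
#' Fixed order: [remove_outliers()] -> [bucket_hourly()] -> [impute_grid()] ->
#' early-warning-score channels on the raw scale -> [normalize_grid()]. Returns
#' the channel grid consumed by window extraction: six normalized vitals, one
#' scaled EWS subscore per charted vital, and the scaled EWS total.
#'
#' @param obs raw observation tibble.
#' @param cohort cohort tibble.
#' @param config an [arrest_config()].
#' @param chart EWS chart, see [mews_chart()].
#' @return A long tibble `stay_id`, `channel`, `hour`, `value`.
#' @export
preprocess_channels <- function(obs, cohort, config = arrest_config(),
                                chart = mews_chart()) {
  config <- as_arrest_config(config)
  grid <- obs %>%
    remove_outliers(config$ranges) %>%
    bucket_hourly(cohort) %>%
    impute_grid()
  ews <- ews_channels(grid, chart)
  vitals <- grid %>%
    normalize_grid(config$normalization, config$fill_value) %>%
    mutate(channel = .data$signal) %>%
    select("stay_id", "channel", "hour", "value")
  bind_rows(vitals, ews) %>%
    mutate(channel = factor(.data$channel, levels = channel_order(chart))) %>%
    arrange(.data$stay_id, .data$channel, .data$hour) %>%
    mutate(channel = as.character(.data$channel))
}

channel_order <- function(chart = mews_chart()) {
  charted <- unique(chart$signal)
  c(vital_signals(), paste0("EWS_", charted), "EWS_TOTAL")
}
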