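#' The early-warning-score chart
#'
#' Loads the banded scoring chart used to convert raw vitals into 0-3
#' subscores. The shipped default codifies the classic Modified Early Warning
#' Score bands for heart rate, respiratory rate, systolic pressure and
#' temperature, extends them with the standard oxygen-saturation bands of the
#' National Early Warning Score, and adds a diastolic-pressure band (an
#' in-package extension so every vital carries a score channel). Each signal's
#' intervals are half-open `[low, high)` and partition the real line; the chart
#' is a plain CSV and can be replaced wholesale.
#'
#' @param path chart CSV with columns `signal`, `low`, `high`, `score`;
#'   defaults to the shipped chart.
#' @return A validated tibble of scoring bands.
#' @export
#' @examples
#' mews_chart()
mews_chart <- function(path = system.file("extdata", "mews_chart.csv",
                                          package = "arrestwatch")) {
  chart <- readr::read_csv(path, col_types = readr::cols(
    signal = readr::col_character(), low = readr::col_double(),
    high = readr::col_double(), score = readr::col_integer()
  ), progress = FALSE)
  validate_chart(chart)
  chart
}

validate_chart <- function(chart) {
  stopifnot(all(c("signal", "low", "high", "score") %in% names(chart)))
  if (any(chart$score < 0 | chart$score > 3)) {
    abort("chart subscores must lie in 0..3")
  }
  for (sig in unique(chart$signal)) {
    b <- chart[chart$signal == sig, ]
    b <- b[order(b$low), ]
    if (b$low[1] != -Inf || b$high[nrow(b)] != Inf ||
        any(b$high[-nrow(b)] != b$low[-1]) || any(b$low >= b$high)) {
      abort(paste0("chart bands for ", sig,
                   " must partition the real line with half-open [low, high) intervals"))
    }
  }
  invisible(chart)
}

#' Score raw vitals against an EWS chart
#'
#' Assigns each raw (pre-normalization) hourly value its 0-3 chart subscore.
#' Signals absent from the chart raise a configuration error. Missing values
#' yield `NA` subscores; the hourly total sums the available subscores, so a
#' fully unobserved vital simply contributes nothing.
#'
#' @param grid imputed hourly grid on the raw clinical scale.
#' @param chart scoring chart from [mews_chart()].
#' @return A long tibble `stay_id`, `signal`, `hour`, `score`, plus rows with
#'   `signal == "TOTAL"` holding the hourly sum.
#' @export
ews_score <- function(grid, chart = mews_chart()) {
  validate_chart(chart)
  uncharted <- setdiff(unique(grid$signal), unique(chart$signal))
  if (length(uncharted)) {
    abort(paste0("no chart bands for signal(s): ",
                 paste(uncharted, collapse = ", ")))
  }
  scored <- grid %>%
    select("stay_id", "signal", "hour", "value") %>%
    mutate(score = chart_lookup(.data$signal, .data$value, chart)) %>%
    select(-"value")
  totals <- scored %>%
    summarise(score = sum(.data$score, na.rm = TRUE),
              .by = c("stay_id", "hour")) %>%
    mutate(signal = "TOTAL")
  bind_rows(scored, totals) %>%
    arrange(.data$stay_id, .data$signal, .data$hour)
}

chart_lookup <- function(signal, value, chart) {
  out <- rep(NA_integer_, length(value))
  for (sig in unique(signal)) {
    b <- chart[chart$signal == sig, ]
    b <- b[order(b$low), ]
    sel <- signal == sig & !is.na(value)
    # half-open [low, high): findInterval on the left edges
    idx <- findInterval(value[sel], b$low)
    out[sel] <- b$score[idx]
  }
  out
}

#' @description
#' `ews_channels()` rescales the subscores into `[0, 1]` model channels:
#' subscores are divided by 3 and the total by `3 * n_charted_signals`.
#' Missing subscores become 0 (an unscored vital raises no alarm points).
#'
#' @rdname ews_score
#' @export
ews_channels <- function(grid, chart = mews_chart()) {
  n_charted <- length(unique(chart$signal))
  ews_score(grid, chart) %>%
    mutate(
      value = dplyr::if_else(.data$signal == "TOTAL",
                             .data$score / (3 * n_charted),
                             .data$score / 3),
      value = dplyr::coalesce(.data$value, 0),
      channel = paste0("EWS_", .data$signal)
    ) %>%
    select("stay_id", "channel", "hour", "value")
}
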