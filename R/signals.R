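#' Vital-sign vocabulary and plausibility ranges
#'
#' The pipeline tracks six bedside vitals: heart rate (`HR`, beats/min),
#' respiratory rate (`RR`, breaths/min), systolic and diastolic blood pressure
#' (`SBP`/`DBP`, mmHg), oxyhemoglobin saturation (`SPO2`, %) and body
#' temperature (`TEMP`, degrees Celsius). All observation tables must use these
#' signal codes.
#'
#' @return `vital_signals()` returns the character vector of recognized signal
#'   codes, in canonical channel order.
#' @export
#' @examples
#' vital_signals()
vital_signals <- function() {
  c("HR", "RR", "SBP", "DBP", "SPO2", "TEMP")
}

#' @description
#' `default_ranges()` returns the per-signal plausibility bounds used both for
#' artifact removal (values outside the range are discarded) and as min-max
#' normalization bounds. They are deliberately conservative physiological
#' limits; override them via the `ranges` / `normalization` entries of
#' [arrest_config()] when a site has its own chart.
#'
#' @return `default_ranges()` returns a tibble with columns `signal`, `low`,
#'   `high` (clinical units).
#' @rdname vital_signals
#' @export
default_ranges <- function() {
  tibble(
    signal = c("HR", "RR", "SBP", "DBP", "SPO2", "TEMP"),
    low    = c(20,   4,    40,    20,    50,     30),
    high   = c(300,  60,   250,   180,   100,    43)
  )
}

check_ranges <- function(ranges, signals = NULL) {
  req <- c("signal", "low", "high")
  if (!all(req %in% names(ranges))) {
    abort("`ranges` must have columns signal, low, high")
  }
  if (any(ranges$low >= ranges$high)) {
    bad <- ranges$signal[ranges$low >= ranges$high]
    abort(paste0("invalid range (low >= high) for signal(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(signals)) {
    missing <- setdiff(signals, ranges$signal)
    if (length(missing)) {
      abort(paste0("no range configured for signal(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  invisible(ranges)
}
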