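#' Read and validate a long-format vital-sign observation table
#'
#' The on-disk format is headered CSV (UTF-8, "." decimal) with columns
#' `stay_id`, `signal`, `t_min` (integer minutes since ICU admission) and
#' `value` (clinical units). Rows are returned sorted by
#' `(stay_id, signal, t_min)` with a stable sort, so equal-time duplicates keep
#' their file order.
#'
#' @param path path to a CSV file.
#' @return A tibble of observations, one row per measurement.
#' @export
read_observations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("stay_id", "signal", "t_min", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("observation file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad_sig <- setdiff(unique(raw$signal), vital_signals())
  if (length(bad_sig)) {
    abort(paste0("unknown signal name(s): ", paste(bad_sig, collapse = ", "),
                 "; expected one of ", paste(vital_signals(), collapse = ", ")))
  }
  t_min <- suppressWarnings(as.numeric(raw$t_min))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(t_min) & !is.na(raw$t_min) | is.na(value) & !is.na(raw$value))
  if (length(bad)) {
    abort(paste0("non-numeric t_min/value at data line(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  obs <- tibble(stay_id = raw$stay_id, signal = raw$signal,
                t_min = as.integer(round(t_min)), value = value)
  validate_observations(obs)
  obs[order(obs$stay_id, obs$signal, obs$t_min, method = "radix"), ]
}

validate_observations <- function(obs) {
  stopifnot(all(c("stay_id", "signal", "t_min", "value") %in% names(obs)))
  if (any(is.na(obs$t_min)) || any(obs$t_min < 0)) {
    abort("t_min must be a non-negative number of minutes since admission")
  }
  if (any(!is.finite(obs$value))) abort("observation values must be finite")
  bad_sig <- setdiff(unique(obs$signal), vital_signals())
  if (length(bad_sig)) {
    abort(paste0("unknown signal name(s): ", paste(bad_sig, collapse = ", ")))
  }
  invisible(obs)
}

#' Read and validate a stay/cohort table
#'
#' Expected CSV columns: `stay_id`, `patient_id`, `age_years`, `icu_subtype`
#' (one of general, cardiac, neuro, trauma, other), `los_hours`, and
#' `ca_event_hours` — a semicolon-separated list of arrest-onset times in hours
#' since admission (empty string = no events). Event lists must be strictly
#' increasing and lie within `[0, los_hours]`.
#'
#' @param path path to a CSV file.
#' @return A tibble with `ca_event_hours` as a list-column of numeric vectors.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    stay_id = readr::col_character(), patient_id = readr::col_character(),
    age_years = readr::col_double(), icu_subtype = readr::col_character(),
    los_hours = readr::col_double(), ca_event_hours = readr::col_character()
  ), progress = FALSE)
  raw$ca_event_hours[is.na(raw$ca_event_hours)] <- ""
  events <- lapply(strsplit(raw$ca_event_hours, ";", fixed = TRUE),
                   function(x) as.numeric(x[nzchar(x)]))
  cohort <- tibble(stay_id = raw$stay_id, patient_id = raw$patient_id,
                   age_years = raw$age_years, icu_subtype = raw$icu_subtype,
                   los_hours = raw$los_hours, ca_event_hours = events)
  validate_cohort(cohort)
  cohort
}

icu_subtypes <- function() c("general", "cardiac", "neuro", "trauma", "other")

validate_cohort <- function(cohort) {
  need <- c("stay_id", "patient_id", "age_years", "icu_subtype", "los_hours",
            "ca_event_hours")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(paste0("cohort table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(cohort$stay_id)) abort("duplicate stay_id in cohort table")
  bad_sub <- setdiff(unique(cohort$icu_subtype), icu_subtypes())
  if (length(bad_sub)) {
    abort(paste0("unknown icu_subtype(s): ", paste(bad_sub, collapse = ", ")))
  }
  for (i in seq_len(nrow(cohort))) {
    ev <- cohort$ca_event_hours[[i]]
    if (!length(ev)) next
    if (is.unsorted(ev, strictly = TRUE)) {
      abort(paste0("ca_event_hours not strictly increasing for stay ",
                   cohort$stay_id[i]))
    }
    if (min(ev) < 0 || max(ev) > cohort$los_hours[i]) {
      abort(paste0("arrest event outside [0, los_hours] for stay ",
                   cohort$stay_id[i]))
    }
  }
  invisible(cohort)
}

#' Write pipeline tables back to disk
#'
#' Writers are exact inverses of the corresponding readers: reading a written
#' table reproduces it field for field.
#'
#' @param x the table to write (observations, cohort, feature matrix or
#'   prediction series).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  validate_observations(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  out <- x
  out$ca_event_hours <- vapply(x$ca_event_hours,
                               function(ev) paste(format(ev, trim = TRUE, scientific = FALSE),
                                                  collapse = ";"),
                               character(1))
  out$ca_event_hours[lengths(x$ca_event_hours) == 0] <- ""
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
write_features <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname write_observations
#' @export
write_predictions <- function(x, path) {
  stopifnot(all(c("stay_id", "t_end", "prob") %in% names(x)))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_predictions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    stay_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
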