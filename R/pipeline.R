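#' Build the labeled feature table from raw tables
#'
#' The full front half of the pipeline: inclusion filtering, outlier removal,
#' hourly bucketing, carry-based imputation, early-warning-score channels,
#' min-max normalization, window labeling and feature assembly. The exclusion
#' log is attached as the `"exclusions"` attribute.
#'
#' @param observations long observation tibble (see [read_observations()]).
#' @param cohort cohort tibble (see [read_cohort()]).
#' @param config an [arrest_config()].
#' @param chart EWS chart (see [mews_chart()]).
#' @return A feature tibble: `stay_id`, `patient_id`, `t_end`, `label`, then
#'   one column per candidate feature.
#' @export
#' @examples
#' d <- synth_cohort(n_patients = 8, ca_fraction = 0.25, seed = 5)
#' fm <- build_features(d$observations, d$cohort)
#' table(fm$label)
build_features <- function(observations, cohort, config = arrest_config(),
                           chart = mews_chart()) {
  config <- as_arrest_config(config)
  kept <- apply_inclusion(cohort, config, obs = observations)
  obs <- observations %>% filter(.data$stay_id %in% kept$stay_id)
  channels <- preprocess_channels(obs, kept, config, chart)
  windows <- label_windows(kept, config)
  if (!nrow(windows)) abort("no labelable windows after inclusion filtering")
  out <- window_features(channels, windows, config, cohort = kept)
  attr(out, "exclusions") <- attr(kept, "exclusions")
  out
}

#' End-to-end synthetic evaluation run
#'
#' Convenience wrapper used by examples, the command-line tool and the
#' acceptance script: generate a synthetic cohort, build features, run the
#' leave-one-patient-out harness.
#'
#' @param n_patients,ca_fraction,seed passed to [synth_cohort()].
#' @param config an [arrest_config()]; its `seed` is set from `seed`.
#' @return A list with `data`, `features` and the `lopo_eval`.
#' @export
run_synthetic_study <- function(n_patients = 400, ca_fraction = 0.04,
                                seed = 1L, config = arrest_config()) {
  config <- as_arrest_config(config)
  config$seed <- as.integer(seed)
  d <- synth_cohort(n_patients = n_patients, ca_fraction = ca_fraction,
                    seed = seed)
  features <- build_features(d$observations, d$cohort, config)
  lopo <- run_lopo(features, d$cohort, config)
  list(data = d, features = features, lopo = lopo)
}
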