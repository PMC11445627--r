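#' Default marginals for the synthetic ICU generator
#'
#' Per-signal baseline mean, between-patient SD, hour-to-hour AR(1) innovation
#' SD, measurement noise SD, and the pre-arrest drift reached at onset (ramped
#' linearly over the final 24 pre-onset hours). Drift directions follow the
#' destabilization pattern seen in arrest cohorts: heart and respiratory rate
#' rise, blood pressure and oxygen saturation fall.
#'
#' @return A tibble with one row per vital signal.
#' @export
synth_signal_params <- function() {
  tibble(
    signal     = c("HR",  "RR",  "SBP", "DBP", "SPO2", "TEMP"),
    mean       = c(86,    19,    120,   64,    96.8,   36.9),
    sd_between = c(2.2,   0.7,   3.0,   2.2,   0.26,   0.09),
    sd_ar      = c(0.5,   0.16,  0.75,  0.5,   0.08,   0.022),
    sd_meas    = c(1.2,   0.6,   1.8,   1.2,   0.3,    0.06),
    drift      = c(15,    4,     -12,   0,     -3,     0)
  )
}

#' Generate a synthetic ICU cohort with rare arrest events
#'
#' Emulates the statistical structure the pipeline assumes: six vital signs
#' sampled irregularly (Poisson observation process, about one sample per hour),
#' hour-scale missing runs, plausible physiological marginals with AR(1)
#' hour-to-hour correlation, lognormal lengths of stay (median about 72 h),
#' rare arrest events, and a linear pre-arrest destabilization ramp over the
#' 24 hours before onset. Occasional artifact spikes outside plausible ranges
#' exercise the outlier filter. Output is deterministic for a given seed.
#'
#' @param n_patients number of patients (one stay per patient).
#' @param ca_fraction fraction of stays with an arrest event (default 0.04,
#'   within the 2.35%-5.8% range typical of ICU subtypes).
#' @param seed integer seed; the generator is a pure function of its arguments.
#' @param signal_params per-signal marginals, see [synth_signal_params()].
#' @param obs_rate expected observations per signal per hour.
#' @param missing_run_prob probability that a stay-signal series contains an
#'   extra multi-hour documentation gap.
#' @param artifact_rate per-observation probability of an out-of-range artifact
#'   spike.
#' @param phi AR(1) coefficient of the hourly latent trajectory.
#' @param los_meanlog,los_sdlog lognormal length-of-stay parameters (hours).
#' @param subtype_probs named probabilities over ICU subtypes.
#' @return A list with tibbles `observations` and `cohort`, both passing the
#'   package validators.
#' @export
#' @examples
#' d <- synth_cohort(n_patients = 20, seed = 7)
#' nrow(d$cohort)
synth_cohort <- function(n_patients = 400,
                         ca_fraction = 0.04,
                         seed = 1L,
                         signal_params = synth_signal_params(),
                         obs_rate = 1.0,
                         missing_run_prob = 0.08,
                         artifact_rate = 0.001,
                         phi = 0.9,
                         los_meanlog = log(72),
                         los_sdlog = 0.45,
                         subtype_probs = c(general = 0.45, cardiac = 0.20,
                                           neuro = 0.15, trauma = 0.10,
                                           other = 0.10)) {
  stopifnot(n_patients >= 1, ca_fraction >= 0, ca_fraction <= 1, obs_rate > 0)
  if (ca_fraction > 0 && ca_fraction * n_patients < 1) {
    warn("ca_fraction * n_patients < 1: expect zero arrest stays")
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("S%04d", seq_len(n_patients))
    los <- pmin(pmax(stats::rlnorm(n_patients, los_meanlog, los_sdlog), 24), 21 * 24)
    is_ca <- stats::runif(n_patients) < ca_fraction
    # arrest stays need room for an onset at >= 36 h plus a pre-onset ramp
    los[is_ca] <- pmax(los[is_ca], 48)
    onset <- rep(NA_real_, n_patients)
    onset[is_ca] <- round(stats::runif(sum(is_ca), 36, los[is_ca] - 1), 1)

    cohort <- tibble(
      stay_id = ids,
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      age_years = round(stats::runif(n_patients, 21, 97), 1),
      icu_subtype = sample(names(subtype_probs), n_patients, replace = TRUE,
                           prob = subtype_probs),
      los_hours = round(los, 1),
      ca_event_hours = lapply(seq_len(n_patients), function(i) {
        if (is_ca[i]) onset[i] else numeric(0)
      })
    )

    obs <- vector("list", n_patients)
    sp <- signal_params
    for (i in seq_len(n_patients)) {
      H <- floor(cohort$los_hours[i])
      per_sig <- vector("list", nrow(sp))
      for (s in seq_len(nrow(sp))) {
        mu <- sp$mean[s] + stats::rnorm(1, 0, sp$sd_between[s])
        innov <- stats::rnorm(H, 0, sp$sd_ar[s])
        latent <- mu + as.numeric(stats::filter(innov, phi, method = "recursive"))
        if (is_ca[i] && sp$drift[s] != 0) {
          h <- seq_len(H) - 0.5  # bucket midpoints
          ramp <- pmax(0, 1 - (onset[i] - h) / 24)
          ramp[h > onset[i]] <- 1
          latent <- latent + sp$drift[s] * pmin(ramp, 1)
        }
        n_obs <- stats::rpois(H, obs_rate)
        if (stats::runif(1) < missing_run_prob && H > 12) {
          run_start <- sample.int(H - 8, 1)
          run_len <- sample(2:8, 1)
          n_obs[run_start:min(H, run_start + run_len - 1)] <- 0
        }
        total <- sum(n_obs)
        if (total == 0) next
        hour_of <- rep.int(seq_len(H) - 1L, n_obs)
        t_min <- as.integer(hour_of * 60L + floor(stats::runif(total, 0, 60)))
        value <- latent[hour_of + 1L] + stats::rnorm(total, 0, sp$sd_meas[s])
        spike <- stats::runif(total) < artifact_rate
        if (any(spike)) {
          value[spike] <- sp$mean[s] * sample(c(3.5, 0.1), sum(spike), replace = TRUE)
        }
        per_sig[[s]] <- tibble(stay_id = ids[i], signal = sp$signal[s],
                               t_min = t_min, value = round(value, 2))
      }
      obs[[i]] <- dplyr::bind_rows(per_sig)
    }
    observations <- dplyr::bind_rows(obs)
    observations <- observations[order(observations$stay_id, observations$signal,
                                       observations$t_min, method = "radix"), ]
    validate_observations(observations)
    validate_cohort(cohort)
    list(observations = observations, cohort = cohort)
  })
}

#' Planted-signal feature bed
#'
#' A tabular oracle for screening and classifier tests: Gaussian features where
#' a known subset is mean-shifted for positive cases. The informative names are
#' returned so recovery can be scored.
#'
#' @param n rows; @param n_informative,n_noise column counts; @param effect
#'   shift (in SDs) applied to informative columns of positive rows;
#'   @param pos_fraction fraction of positive labels; @param seed integer seed.
#' @return list with tibble `X`, integer vector `y` and character
#'   `informative`.
#' @export
planted_feature_bed <- function(n = 1000, n_informative = 10, n_noise = 90,
                                effect = 1.5, pos_fraction = 0.3, seed = 1L) {
  stopifnot(n_informative >= 1, n_noise >= 0)
  withr::with_seed(as.integer(seed), {
    y <- stats::rbinom(n, 1, pos_fraction)
    p <- n_informative + n_noise
    X <- matrix(stats::rnorm(n * p), n, p)
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + outer(y, rep(effect, n_informative))
    informative <- sprintf("inf_%02d", seq_len(n_informative))
    noise <- if (n_noise) sprintf("noise_%02d", seq_len(n_noise)) else character(0)
    colnames(X) <- c(informative, noise)
    list(X = as_tibble(X), y = y, informative = informative)
  })
}
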