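#' Pipeline configuration
#'
#' One flat configuration object drives every stage: preprocessing ranges,
#' window geometry, feature design, screening, the classifier and the
#' evaluation harness. Unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' Key groups (defaults in parentheses):
#'
#' * **Time geometry** — `window_hours` (12) lookback length; `horizon_hours`
#'   (24) alarm horizon; `resume_gap_hours` (24) hours after an arrest before
#'   window emission resumes.
#' * **Cohort** — `min_age`/`max_age` (18/100, exclusive bounds);
#'   `strict_event_timing` (FALSE) additionally requires an observation in the
#'   hour before each arrest onset.
#' * **Preprocessing** — `ranges`, `normalization` (both [default_ranges()]);
#'   `fill_value` (0.5) normalized value used for fully unobserved signals.
#' * **Features** — `segment_plan` (tiled 1-4, 5-8, 9-12, 1-6, 7-12, 1-12);
#'   `stats` (mean, median, min, max, sd, skewness); `gini` (TRUE).
#' * **Screening** — `screen` (TRUE); `n_keep_frac` (0.15 of candidates for the
#'   recursive eliminator); `rfe_step` (0.10 of current features dropped per
#'   iteration); `vote_threshold` (2 = both methods must agree);
#'   `boruta_max_runs` (15), `boruta_alpha` (0.05); `screen_row_cap` (1600
#'   rows used to fit importance models — every arrest window is kept, only
#'   the majority class is downsampled); `screen_nrounds` (15),
#'   `screen_max_depth` (3) boosting settings for the importance engine.
#' * **Classifier** — `backend` ("attentive" or "xgboost"); `class_weight_ca`
#'   (100); `learning_rate` (0.01); `n_steps` (3); `width` (8); `relaxation`
#'   (1.3); `sparsity` (1e-3); `weight_decay` (1.0, decoupled L2 — hourly
#'   windows within a patient are strongly correlated, so the effective sample
#'   size is patients, not windows); `epochs` (60); `patience` (10);
#'   `batch_size` (2048); `val_frac` (0.15, held out by patient when groups
#'   are available); `xgb_nrounds` (150), `xgb_max_depth` (4), `xgb_eta` (0.1)
#'   for the fallback backend.
#' * **Evaluation** — `threshold` (0.5) alarm operating point; `k_folds` (10);
#'   `pooled_auroc` (FALSE: AUROC reported as per-fold mean, pooled available
#'   behind this flag).
#' * `seed` (1) master seed.
#'
#' @param ... name-value pairs overriding the defaults above.
#' @return A named list of class `arrest_config`.
#' @export
#' @examples
#' cfg <- arrest_config(class_weight_ca = 10, k_folds = 5)
#' cfg$k_folds
arrest_config <- function(...) {
  defaults <- list(
    window_hours        = 12L,
    horizon_hours       = 24L,
    resume_gap_hours    = 24L,
    min_age             = 18,
    max_age             = 100,
    strict_event_timing = FALSE,
    ranges              = default_ranges(),
    normalization       = default_ranges(),
    fill_value          = 0.5,
    segment_plan        = list(c(1L, 4L), c(5L, 8L), c(9L, 12L),
                               c(1L, 6L), c(7L, 12L), c(1L, 12L)),
    stats               = c("mean", "median", "min", "max", "sd", "skewness"),
    gini                = TRUE,
    screen              = TRUE,
    n_keep_frac         = 0.15,
    rfe_step            = 0.10,
    vote_threshold      = 2L,
    boruta_max_runs     = 15L,
    boruta_alpha        = 0.05,
    screen_row_cap      = 1600L,
    screen_nrounds      = 15L,
    screen_max_depth    = 3L,
    backend             = "attentive",
    class_weight_ca     = 100,
    learning_rate       = 0.01,
    n_steps             = 3L,
    width               = 8L,
    relaxation          = 1.3,
    sparsity            = 1e-3,
    weight_decay        = 1.0,
    epochs              = 60L,
    patience            = 10L,
    batch_size          = 2048L,
    val_frac            = 0.15,
    xgb_nrounds         = 150L,
    xgb_max_depth       = 4L,
    xgb_eta             = 0.1,
    threshold           = 0.5,
    k_folds             = 10L,
    pooled_auroc        = FALSE,
    seed                = 1L
  )
  user <- list(...)
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == "")) {
      abort("all configuration overrides must be named")
    }
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      abort(paste0("unknown configuration key(s): ",
                   paste(unknown, collapse = ", ")))
    }
    defaults[names(user)] <- user
  }
  check_ranges(defaults$ranges)
  check_ranges(defaults$normalization)
  stopifnot(defaults$window_hours >= 1, defaults$horizon_hours >= 1,
            defaults$class_weight_ca > 0, defaults$n_steps >= 1)
  structure(defaults, class = "arrest_config")
}

#' @export
print.arrest_config <- function(x, ...) {
  cat("<arrest_config>\n")
  scalar <- vapply(x, function(v) is.atomic(v) && length(v) == 1, logical(1))
  for (nm in names(x)[scalar]) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  cat("  (+ ranges, normalization, segment_plan, stats tables)\n")
  invisible(x)
}

as_arrest_config <- function(config) {
  if (inherits(config, "arrest_config")) return(config)
  if (is.null(config)) return(arrest_config())
  do.call(arrest_config, config)
}
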