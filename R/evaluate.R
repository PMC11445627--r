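#' Leave-one-patient-out fold assignment
#'
#' Partitions patients (never windows) into `k` folds, stratified by whether
#' the patient ever arrests so arrest patients spread evenly. Deterministic
#' given `seed`.
#'
#' @param cohort cohort tibble.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return A tibble `patient_id`, `fold` (1-based).
#' @export
make_folds <- function(cohort, k = 10L, seed = 1L) {
  patients <- cohort %>%
    summarise(has_ca = any(lengths(.data$ca_event_hours) > 0),
              .by = "patient_id")
  if (k > nrow(patients)) abort("more folds than patients")
  n_ca <- sum(patients$has_ca)
  if (n_ca > 0 && n_ca < k) {
    warn(paste0("only ", n_ca, " arrest patient(s) for ", k,
                " folds; some folds will lack arrest events"))
  }
  withr::with_seed(as.integer(seed), {
    # shuffled arrest patients first, then the rest, dealt round-robin over a
    # shuffled fold order: arrest patients land in distinct folds while fold
    # sizes stay globally balanced
    ids <- c(sample(patients$patient_id[patients$has_ca]),
             sample(patients$patient_id[!patients$has_ca]))
    tibble(patient_id = ids, fold = rep_len(sample.int(k), length(ids))) %>%
      arrange(.data$patient_id)
  })
}

fit_and_replay <- function(train, test, cohort, config, seed, fold = NA_integer_) {
  ptr <- feature_parts(train)
  pte <- feature_parts(test)
  selected <- colnames(ptr$X)
  screening <- NULL
  if (isTRUE(config$screen)) {
    screening <- screen_features(ptr$X, ptr$y, config, seed = seed)
    selected <- attr(screening, "selected")
  }
  groups <- if ("patient_id" %in% names(ptr$index)) ptr$index$patient_id
  model <- ca_fit(ptr$X[, selected, drop = FALSE], ptr$y, config, seed = seed,
                  groups = groups)
  prob <- predict(model, pte$X[, selected, drop = FALSE])
  predictions <- bind_cols(pte$index, tibble(label = pte$y, prob = prob))
  if (!is.na(fold)) predictions$fold <- fold
  list(model = model, predictions = predictions, selected = selected,
       screening = screening)
}

#' Pseudo-real-time leave-one-patient-out evaluation
#'
#' For each fold: screen features on the training patients only, fit the
#' cost-sensitive classifier on their windows, then replay every test stay
#' hour by hour and score the resulting alarm series. No window of a test
#' patient ever enters its fold's training data, and screening is repeated
#' inside every fold to avoid selection leakage.
#'
#' @param features feature table from [window_features()] (must carry
#'   `patient_id`).
#' @param cohort cohort tibble.
#' @param config an [arrest_config()]; `k_folds`, `threshold`, `screen`,
#'   `seed` and the classifier keys apply.
#' @return A `lopo_eval` object: per-fold metrics (`$folds`), pooled hourly
#'   predictions (`$predictions`), fold assignment, per-fold selected feature
#'   sets, and the configuration. `tidy()` returns per-fold metrics,
#'   `glance()` the mean and SD summary.
#' @export
run_lopo <- function(features, cohort, config = arrest_config()) {
  config <- as_arrest_config(config)
  if (!"patient_id" %in% names(features)) {
    features <- features %>%
      left_join(select(cohort, "stay_id", "patient_id"), by = "stay_id") %>%
      select("stay_id", "patient_id", dplyr::everything())
  }
  folds <- make_folds(cohort, config$k_folds, config$seed)
  features <- features %>% inner_join(folds, by = "patient_id")
  fold_metrics <- vector("list", config$k_folds)
  preds <- vector("list", config$k_folds)
  sel <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    test <- features %>% filter(.data$fold == f) %>% select(-"fold")
    train <- features %>% filter(.data$fold != f) %>% select(-"fold")
    if (!nrow(test)) next
    res <- tryCatch(
      fit_and_replay(train, test, cohort, config, seed = config$seed + f,
                     fold = f),
      error = function(e) abort(paste0("fold ", f, ": ", conditionMessage(e)))
    )
    m <- event_metrics(res$predictions, cohort, config$threshold,
                       config$horizon_hours)
    fold_metrics[[f]] <- bind_cols(tibble(fold = f), m)
    preds[[f]] <- res$predictions
    sel[[f]] <- res$selected
    rm(res, train, test)
    gc(verbose = FALSE)
  }
  structure(list(folds = bind_rows(fold_metrics),
                 predictions = bind_rows(preds),
                 fold_assignment = folds,
                 selected = sel,
                 config = config),
            class = "lopo_eval")
}

#' @export
print.lopo_eval <- function(x, ...) {
  cat("<lopo_eval>", nrow(x$folds), "folds,", nrow(x$predictions),
      "replayed windows\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.lopo_eval <- function(x, ...) x$folds

#' @export
glance.lopo_eval <- function(x, ...) {
  metrics <- c("auroc", "sensitivity", "specificity", "event_recall",
               "false_alarm_rate", "brier")
  out <- tibble(.rows = 1)
  for (m in metrics) {
    v <- x$folds[[m]]
    out[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
    out[[paste0(m, "_sd")]] <- stats::sd(v, na.rm = TRUE)
  }
  if (isTRUE(x$config$pooled_auroc)) {
    out$auroc_pooled <- auroc(x$predictions$prob, x$predictions$label)
  }
  out$n_windows <- nrow(x$predictions)
  out
}

#' Post hoc subgroup evaluation by ICU subtype
#'
#' Partitions the already-computed test predictions by each stay's ICU
#' subtype and rescores them; no retraining, mirroring a deployment where one
#' model serves every unit.
#'
#' @param lopo a `lopo_eval` from [run_lopo()].
#' @param cohort cohort tibble with `icu_subtype`.
#' @return A tibble of [event_metrics()] rows, one per subtype.
#' @export
run_subgroup <- function(lopo, cohort) {
  preds <- lopo$predictions %>%
    left_join(select(cohort, "stay_id", "icu_subtype"), by = "stay_id")
  subtypes <- sort(unique(preds$icu_subtype))
  bind_rows(lapply(subtypes, function(st) {
    sub <- preds %>% filter(.data$icu_subtype == st)
    bind_cols(tibble(icu_subtype = st),
              event_metrics(sub, cohort, lopo$config$threshold,
                            lopo$config$horizon_hours))
  }))
}

#' Cross-dataset external validation
#'
#' Fits once on the full training dataset (with fold-free screening) and
#' replays every stay of the test dataset. Feature schemas are intersected;
#' features absent from either side are dropped, and an empty intersection is
#' an error.
#'
#' @param train_features,train_cohort source dataset.
#' @param test_features,test_cohort target dataset.
#' @param config an [arrest_config()].
#' @return A one-row tibble of [event_metrics()], with the fitted model and
#'   predictions in attributes `"model"` and `"predictions"`.
#' @export
run_crossdata <- function(train_features, train_cohort,
                          test_features, test_cohort,
                          config = arrest_config()) {
  config <- as_arrest_config(config)
  meta <- c("stay_id", "patient_id", "t_end", "label")
  shared <- intersect(setdiff(names(train_features), meta),
                      setdiff(names(test_features), meta))
  if (!length(shared)) abort("no shared features between datasets")
  train <- train_features[, c(intersect(meta, names(train_features)), shared)]
  test <- test_features[, c(intersect(meta, names(test_features)), shared)]
  res <- fit_and_replay(train, test, test_cohort, config, seed = config$seed)
  out <- event_metrics(res$predictions, test_cohort, config$threshold,
                       config$horizon_hours)
  attr(out, "model") <- res$model
  attr(out, "predictions") <- res$predictions
  out
}

#' Compare models on per-fold metrics
#'
#' Kruskal-Wallis test across models followed by Tukey honestly-significant-
#' difference post hoc contrasts on the fold-level metric values, at a 5%
#' significance level.
#'
#' @param fold_metrics long tibble with columns `model`, `fold`, `value`.
#' @param alpha significance level (default 0.05).
#' @return A `model_comparison` list: `$kruskal` (statistic, df, p.value) and
#'   `$hsd` (pairwise contrasts with adjusted p-values and a `significant`
#'   flag). `tidy()` returns the contrasts, `glance()` the omnibus test.
#' @export
compare_models <- function(fold_metrics, alpha = 0.05) {
  stopifnot(all(c("model", "value") %in% names(fold_metrics)))
  models <- unique(fold_metrics$model)
  if (length(models) < 2) abort("need at least 2 models to compare")
  n_per <- fold_metrics %>% count(.data$model)
  if (any(n_per$n < 3)) abort("need at least 3 folds per model")
  if (stats::sd(fold_metrics$value) == 0) {
    warn("all metric values identical; comparison is degenerate")
    return(structure(list(
      kruskal = tibble(statistic = NA_real_, df = length(models) - 1L,
                       p.value = NA_real_),
      hsd = tibble(), alpha = alpha, degenerate = TRUE
    ), class = "model_comparison"))
  }
  df <- data.frame(model = factor(fold_metrics$model),
                   value = fold_metrics$value)
  kw <- stats::kruskal.test(value ~ model, data = df)
  hsd <- stats::TukeyHSD(stats::aov(value ~ model, data = df))$model
  hsd_tbl <- tibble(contrast = rownames(hsd),
                    estimate = hsd[, "diff"],
                    conf.low = hsd[, "lwr"], conf.high = hsd[, "upr"],
                    adj.p.value = hsd[, "p adj"]) %>%
    mutate(significant = .data$adj.p.value < alpha)
  structure(list(
    kruskal = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p.value = kw$p.value),
    hsd = hsd_tbl, alpha = alpha, degenerate = FALSE
  ), class = "model_comparison")
}

#' @export
tidy.model_comparison <- function(x, ...) x$hsd

#' @export
glance.model_comparison <- function(x, ...) x$kruskal

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> Kruskal-Wallis H =",
      signif(x$kruskal$statistic, 4), ", p =", signif(x$kruskal$p.value, 3), "\n")
  if (nrow(x$hsd)) print(x$hsd)
  invisible(x)
}
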