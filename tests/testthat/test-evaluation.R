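test_that("fold assignment partitions patients deterministically", {
  cohort <- tibble::tibble(
    stay_id = sprintf("S%02d", 1:10),
    patient_id = sprintf("P%02d", 1:10),
    age_years = 50, icu_subtype = "general", los_hours = 50,
    ca_event_hours = c(lapply(1:3, function(i) 40), lapply(4:10, function(i) numeric(0)))
  )
  f <- suppressWarnings(make_folds(cohort, k = 10, seed = 1))
  expect_equal(sort(f$fold), 1:10)  # singleton folds
  expect_equal(f, suppressWarnings(make_folds(cohort, k = 10, seed = 1)))
  expect_warning(make_folds(cohort, k = 5, seed = 1), "arrest patient")
  expect_error(make_folds(cohort, k = 11, seed = 1), "more folds")

  # stratification balances arrest patients across folds
  big <- tibble::tibble(
    stay_id = sprintf("S%03d", 1:60),
    patient_id = sprintf("P%03d", 1:60),
    age_years = 50, icu_subtype = "general", los_hours = 50,
    ca_event_hours = c(lapply(1:10, function(i) 40),
                       lapply(11:60, function(i) numeric(0)))
  )
  fb <- make_folds(big, k = 5, seed = 3)
  ca_per_fold <- table(fb$fold[fb$patient_id %in% sprintf("P%03d", 1:10)])
  expect_true(all(ca_per_fold == 2))
})

test_that("alarm metrics reproduce the textbook formulas", {
  # 10 alarms, 7 true: FAR = 1 - 7/10; 4 events, 3 captured: ER = 0.75
  cohort <- tibble::tibble(
    stay_id = sprintf("S%d", 1:4),
    patient_id = sprintf("P%d", 1:4),
    age_years = 50, icu_subtype = "general", los_hours = 80,
    ca_event_hours = list(30, 40, 50, 60)
  )
  preds <- dplyr::bind_rows(
    tibble::tibble(stay_id = "S1", t_end = 12:18,
                   label = as.integer(12:18 >= 6 & 12:18 < 30),
                   prob = c(1, 1, 1, 0, 0, 0, 0)),       # 3 true alarms, captured
    tibble::tibble(stay_id = "S2", t_end = 17:22,
                   label = 1L, prob = c(1, 1, 1, 1, 0, 0)), # 4 true alarms, captured
    tibble::tibble(stay_id = "S3", t_end = 27:29,
                   label = 1L, prob = 0),                  # no alarm: missed
    tibble::tibble(stay_id = "S4", t_end = 37:39,
                   label = 1L, prob = c(1, 0, 0))          # 1 true alarm, captured
  )
  extra_false <- tibble::tibble(stay_id = "S1", t_end = 56:57, label = 0L,
                                prob = 1)
  m <- event_metrics(dplyr::bind_rows(preds, extra_false), cohort, 0.5, 24)
  expect_equal(m$n_alarm, 10L)
  expect_equal(m$n_true, 8L)
  expect_equal(m$false_alarm_rate, 1 - 8 / 10)
  expect_equal(m$event_recall, 3 / 4)

  # no alarms at all: the false-alarm ratio is undefined, not zero
  quiet <- dplyr::mutate(preds, prob = 0)
  mq <- event_metrics(quiet, cohort, 0.5, 24)
  expect_true(is.na(mq$false_alarm_rate))
  expect_equal(mq$event_recall, 0)
})

test_that("alarm metrics agree exactly with the brute-force replay oracle", {
  for (seed in 1:30) {
    inst <- random_eval_instance(seed)
    if (!nrow(inst$predictions)) next
    tau <- withr::with_seed(seed + 1000, runif(1, 0.2, 0.8))
    got <- event_metrics(inst$predictions, inst$cohort, tau, 24)
    events <- setNames(inst$cohort$ca_event_hours, inst$cohort$stay_id)
    events <- events[lengths(events) > 0]
    want <- oracle_event_metrics(as.data.frame(inst$predictions), events, tau, 24)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], info = f)
  }
})

test_that("the rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    for (rep in 1:5) {
      y <- rbinom(80, 1, 0.3)
      if (length(unique(y)) < 2) next
      prob <- runif(80)
      prob[sample(80, 20)] <- round(prob[sample(80, 20)], 1)  # force ties
      ref <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
      expect_equal(auroc(prob, y), ref, tolerance = 1e-12)
    }
  })
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("raising the threshold never adds alarms", {
  inst <- random_eval_instance(99)
  taus <- seq(0, 1, by = 0.1)
  n_alarm <- vapply(taus, function(tau) {
    event_metrics(inst$predictions, inst$cohort, tau, 24)$n_alarm
  }, numeric(1))
  expect_true(all(diff(n_alarm) <= 0))
})

test_that("LOPO keeps test patients out of training and screens per fold", {
  d <- synth_cohort(n_patients = 30, ca_fraction = 0.2, seed = 61)
  fm <- slim_features(build_features(d$observations, d$cohort))
  cfg <- arrest_config(k_folds = 3, epochs = 10L, patience = 3L,
                       screen = FALSE, seed = 7)
  lopo <- suppressWarnings(run_lopo(fm, d$cohort, cfg))
  # every window of every patient is predicted exactly once, in its own fold
  expect_equal(nrow(lopo$predictions), nrow(fm))
  joined <- dplyr::left_join(lopo$predictions,
                             lopo$fold_assignment, by = "patient_id")
  expect_equal(joined$fold.x, joined$fold.y)
  expect_true(all(lopo$folds$auroc >= 0 & lopo$folds$auroc <= 1, na.rm = TRUE))
})

test_that("fold-internal screening is reproducible from the training half only", {
  d <- synth_cohort(n_patients = 24, ca_fraction = 0.25, seed = 62)
  fm <- build_features(d$observations, d$cohort)
  cfg <- arrest_config(k_folds = 2, epochs = 8L, patience = 3L,
                       screen_row_cap = 800L, boruta_max_runs = 6L, seed = 5)
  lopo <- suppressWarnings(run_lopo(fm, d$cohort, cfg))
  folds <- lopo$fold_assignment
  for (f in 1:2) {
    train <- fm[fm$patient_id %in% folds$patient_id[folds$fold != f], ]
    parts <- feature_parts(train)
    redo <- screen_features(parts$X, parts$y, cfg, seed = cfg$seed + f)
    expect_equal(attr(redo, "selected"), lopo$selected[[f]])
  }
})

test_that("subgroup partitions reconcile with the pooled confusion counts", {
  d <- synth_cohort(n_patients = 30, ca_fraction = 0.2, seed = 63)
  fm <- slim_features(build_features(d$observations, d$cohort))
  cfg <- arrest_config(k_folds = 3, epochs = 10L, patience = 3L,
                       screen = FALSE, seed = 7)
  lopo <- suppressWarnings(run_lopo(fm, d$cohort, cfg))
  sub <- run_subgroup(lopo, d$cohort)
  pooled <- event_metrics(lopo$predictions, d$cohort, cfg$threshold, 24)
  expect_equal(sum(sub$n_windows), pooled$n_windows)
  expect_equal(sum(sub$n_alarm), pooled$n_alarm)
  expect_equal(sum(sub$n_events), pooled$n_events)
  expect_equal(sum(sub$n_captured), pooled$n_captured)
})

test_that("cross-dataset validation intersects schemas and degenerates to resubstitution", {
  d <- synth_cohort(n_patients = 20, ca_fraction = 0.25, seed = 64)
  fm <- slim_features(build_features(d$observations, d$cohort))
  cfg <- arrest_config(epochs = 10L, patience = 3L, screen = FALSE, seed = 7)
  res <- run_crossdata(fm, d$cohort, fm, d$cohort, cfg)
  expect_equal(res$n_windows, nrow(fm))
  expect_gt(res$auroc, 0.5)  # resubstitution should beat chance

  other <- fm
  names(other) <- sub("^HR", "XR", names(other))
  shared <- run_crossdata(fm, d$cohort, other, d$cohort, cfg)
  expect_equal(shared$n_windows, nrow(fm))  # non-shared features dropped

  disjoint <- fm[, c("stay_id", "patient_id", "t_end", "label")]
  disjoint$only_here <- 1
  expect_error(run_crossdata(fm[, c("stay_id", "patient_id", "t_end", "label",
                                    "HR_1h")],
                             d$cohort, disjoint, d$cohort, cfg),
               "no shared features")
})

test_that("model comparison detects separation and handles degenerate input", {
  same <- tibble::tibble(model = rep(c("a", "b"), each = 10), fold = rep(1:10, 2),
                         value = rep(seq(0.7, 0.79, 0.01), 2))
  cmp <- compare_models(same)
  expect_gt(cmp$kruskal$p.value, 0.9)

  apart <- tibble::tibble(
    model = rep(c("a", "b"), each = 10),
    value = c(rnorm(10, 0.7, 0.02), rnorm(10, 0.76, 0.02))
  )
  cmp2 <- compare_models(apart)
  expect_lt(cmp2$kruskal$p.value, 0.05)
  expect_true(all(tidy(cmp2)$significant))

  expect_error(compare_models(tibble::tibble(model = "a", value = 1:5)),
               "at least 2 models")
  expect_error(compare_models(tibble::tibble(model = rep(c("a", "b"), 2),
                                             value = rep(1, 4))),
               "at least 3 folds")
  expect_warning(cmp3 <- compare_models(
    tibble::tibble(model = rep(c("a", "b"), each = 5), value = rep(0.5, 10))),
    "degenerate")
  expect_true(cmp3$degenerate)
})
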