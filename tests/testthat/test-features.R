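mk_wm <- function(mat, channels, W = 12L) {
  colnames(mat) <- as.vector(t(outer(channels, seq_len(W),
                                     function(ch, h) paste0(ch, "_", h, "h"))))
  list(mat = mat, channels = channels,
       windows = tibble::tibble(stay_id = "S", t_end = seq_len(nrow(mat)) + 11L,
                                label = 0L),
       window_hours = W)
}

test_that("the default design yields 156 + 468 + 13 = 637 named candidates", {
  cfg <- arrest_config()
  schema <- feature_schema(cfg)
  expect_length(schema, 637)
  expect_length(grep("_\\d+h$", schema[!startsWith(schema, "Gini_")]), 156)
  expect_length(grep("h_(Mean|Median|Min|Max|SD|Skewness)$", schema), 468)
  expect_length(grep("^Gini_", schema), 13)
  expect_false(anyDuplicated(schema) > 0)

  # schema is a pure function of configuration, and data-driven names match it
  d <- synth_cohort(n_patients = 4, ca_fraction = 0, seed = 13)
  ch <- preprocess_channels(d$observations, d$cohort)
  w <- label_windows(d$cohort)
  fm <- window_features(ch, w, cfg, cohort = d$cohort)
  expect_equal(setdiff(names(fm), c("stay_id", "patient_id", "t_end", "label")),
               schema)
})

test_that("time-step features index the lookback window 1-based", {
  withr::with_seed(5, {
    ch_grid <- tidyr::expand_grid(stay_id = "S", channel = c("A", "B"),
                                  hour = 0:19)
    ch_grid$value <- round(runif(nrow(ch_grid)), 3)
  })
  windows <- tibble::tibble(stay_id = "S", t_end = c(12L, 15L), label = 0L)
  wm <- extract_window_matrix(ch_grid, windows, 12L)
  ts <- timestep_features(wm)
  a <- ch_grid$value[ch_grid$channel == "A"]
  # window ending at hour 15 looks back over buckets 3..14; A_8h is bucket 10
  expect_equal(ts[2, "A_8h"], unname(a[11]), ignore_attr = TRUE)
  expect_equal(ts[1, "A_1h"], unname(a[1]), ignore_attr = TRUE)
  expect_equal(ncol(ts), 24)
})

test_that("segment statistics match hand computation and e1071 conventions", {
  skip_if_not_installed("e1071")
  x <- matrix(c(0, 1, 1, 0,
                0.2, 0.2, 0.2, 0.2), 2, 4, byrow = TRUE)
  wm <- mk_wm(cbind(x, matrix(0, 2, 8)), "A")
  mr <- multiresolution_features(wm, segment_plan = list(c(1L, 4L)),
                                 stats = c("mean", "median", "min", "max", "sd"))
  expect_equal(unname(mr[1, ]), c(0.5, 0.5, 0, 1, 0.5))  # population SD
  expect_equal(unname(mr[2, ]), c(0.2, 0.2, 0.2, 0.2, 0))

  withr::with_seed(8, {
    r <- matrix(rnorm(60), 5, 12)
    wm <- mk_wm(r, "A")
    sk <- multiresolution_features(wm, segment_plan = list(c(1L, 12L)),
                                   stats = "skewness")
    expect_equal(unname(sk[, 1]),
                 apply(r, 1, e1071::skewness, type = 2), tolerance = 1e-12)
  })

  expect_error(multiresolution_features(wm, segment_plan = list(c(0L, 4L))),
               "segment")
  expect_error(multiresolution_features(wm, segment_plan = list(c(1L, 13L))),
               "segment")
})

test_that("Gini features match the pairwise brute-force oracle", {
  withr::with_seed(17, {
    series <- matrix(runif(200 * 12), 200, 12)
    wm <- mk_wm(series, "A")
    gv <- gini_features(wm)[, 1]
    for (i in seq_len(200)) {
      expect_equal(gv[i], 1 - 2 * oracle_gini(series[i, ]) / 11,
                   tolerance = 1e-12)
    }
  })

  # a stable series has minimal dispersion: G = 0, GV = 1
  wm <- mk_wm(matrix(0.7, 1, 12), "A")
  expect_equal(unname(gini_features(wm)[1, 1]), 1)

  # a single spike raises G, lowering GV
  flat <- rep(0.5, 12); spiked <- flat; spiked[6] <- 1
  wm2 <- mk_wm(rbind(flat, spiked), "A")
  gv2 <- gini_features(wm2)[, 1]
  expect_lt(gv2[2], gv2[1])
  expect_equal(oracle_gini(c(0, 1)), 0.5)  # pinned n = 2 example
})

test_that("full-window statistics are permutation invariant, time steps are not", {
  withr::with_seed(23, {
    x <- runif(12)
    perm <- sample(12)
    wm_a <- mk_wm(matrix(x, 1), "A")
    wm_b <- mk_wm(matrix(x[perm], 1), "A")
    full_plan <- list(c(1L, 12L))
    expect_equal(multiresolution_features(wm_a, full_plan),
                 multiresolution_features(wm_b, full_plan))
    expect_equal(gini_features(wm_a), gini_features(wm_b))
    expect_false(isTRUE(all.equal(timestep_features(wm_a),
                                  timestep_features(wm_b))))
  })
})

test_that("assembly rejects duplicate names and empty channel sets", {
  d <- synth_cohort(n_patients = 3, ca_fraction = 0, seed = 19)
  ch <- preprocess_channels(d$observations, d$cohort)
  w <- label_windows(d$cohort)
  expect_error(window_features(ch[0, ], w), "no channels|no grid")
  fm <- window_features(ch, w, cohort = d$cohort)
  expect_false(anyDuplicated(names(fm)) > 0)
})
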