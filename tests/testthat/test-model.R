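small_bed <- function(seed = 3, n = 400) {
  planted_feature_bed(n = n, n_informative = 4, n_noise = 8, effect = 1.2,
                      seed = seed)
}

quick_cfg <- function(...) arrest_config(epochs = 30L, patience = 8L, ...)

test_that("analytic gradients match finite differences", {
  aw <- asNamespace("arrestwatch")
  withr::with_seed(2, {
    n <- 7; p <- 5; K <- 3; d <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.5)
    w <- ifelse(y == 1, 3, 1)
    par <- aw$att_init(p, d, K)
    lg <- aw$att_loss_grad(par, X, y, w, K, 1.3, 1e-2)
    for (nm in names(par)) {
      for (rep in 1:4) {
        idx <- sample(length(par[[nm]]), 1)
        eps <- 1e-6
        p1 <- par; p1[[nm]][idx] <- p1[[nm]][idx] + eps
        p2 <- par; p2[[nm]][idx] <- p2[[nm]][idx] - eps
        num <- (aw$att_loss_grad(p1, X, y, w, K, 1.3, 1e-2)$loss -
                aw$att_loss_grad(p2, X, y, w, K, 1.3, 1e-2)$loss) / (2 * eps)
        an <- lg$grad[[nm]][idx]
        expect_lt(abs(an - num) / max(1e-6, abs(an) + abs(num)), 1e-4)
      }
    }
  })
})

test_that("training is deterministic and the loss reduces to plain CE", {
  bed <- small_bed()
  m1 <- ca_fit(bed$X, bed$y, quick_cfg(), seed = 6)
  m2 <- ca_fit(bed$X, bed$y, quick_cfg(), seed = 6)
  expect_equal(predict(m1, bed$X), predict(m2, bed$X))

  prob <- c(0.2, 0.9, 0.6)
  y <- c(0, 1, 1)
  plain <- -mean(y * log(prob + 1e-8) + (1 - y) * log(1 - prob + 1e-8))
  expect_equal(weighted_cross_entropy(prob, y), plain)
  expect_gt(weighted_cross_entropy(prob, y, ifelse(y == 1, 100, 1)), 0)
})

test_that("prediction respects the schema contract", {
  bed <- small_bed()
  m <- ca_fit(bed$X, bed$y, quick_cfg(), seed = 6)
  p <- predict(m, bed$X)
  expect_true(all(p >= 0 & p <= 1))
  # duplicate rows give identical outputs
  dup <- bed$X[c(1, 1, 2), ]
  pd <- predict(m, dup)
  expect_equal(pd[1], pd[2])
  # column order is irrelevant because alignment is by name
  shuffled <- bed$X[, sample(ncol(bed$X))]
  expect_equal(predict(m, shuffled), p)
  expect_error(predict(m, bed$X[, -1]), "missing")
  extra <- bed$X; extra$zzz <- 1
  expect_error(predict(m, extra), "unexpected")
  bad <- bed$X; bad[[1]][1] <- NA
  expect_error(ca_fit(bad, bed$y, quick_cfg()), "inf_01")
  expect_error(ca_fit(bed$X, rep(0, nrow(bed$X)), quick_cfg()), "both classes")
})

test_that("decision masks are normalized attributions that find the signal", {
  bed <- small_bed(n = 600)
  m <- ca_fit(bed$X, bed$y, quick_cfg(), seed = 6)
  ex <- ca_explain(m, bed$X)
  expect_length(ex$masks, arrest_config()$n_steps)
  for (mk in ex$masks) {
    expect_true(all(mk >= 0))
    expect_equal(rowSums(mk), rep(1, nrow(bed$X)), tolerance = 1e-6)
  }
  expect_true(all(ex$importance >= 0))
  expect_equal(rowSums(ex$importance), rep(1, nrow(bed$X)), tolerance = 1e-6)
  # planted informative features dominate the global ranking
  top <- head(ex$global$feature, 6)
  expect_gte(length(intersect(top, bed$informative)), 2)

  # with a single decision step the aggregate importance is that step's mask
  m1 <- ca_fit(bed$X, bed$y, quick_cfg(n_steps = 1L), seed = 6)
  ex1 <- ca_explain(m1, bed$X[1:20, ])
  expect_equal(ex1$importance, ex1$masks[[1]], tolerance = 1e-12)

  # xgboost backend honors the same contract
  mx <- ca_fit(bed$X, bed$y, quick_cfg(backend = "xgboost"), seed = 6)
  exx <- ca_explain(mx, bed$X[1:10, ])
  expect_equal(rowSums(exx$importance), rep(1, 10), tolerance = 1e-6)
})

test_that("raising the arrest-class weight does not lower arrest recall", {
  bed <- small_bed(seed = 12, n = 500)
  tr <- 1:350; te <- 351:500
  recall_at <- function(w) {
    m <- ca_fit(bed$X[tr, ], bed$y[tr], quick_cfg(class_weight_ca = w), seed = 4)
    p <- predict(m, bed$X[te, ])
    mean(p[bed$y[te] == 1] >= 0.5)
  }
  r <- vapply(c(1, 10, 100), recall_at, numeric(1))
  n_pos <- sum(bed$y[te] == 1)
  tol <- 1 / n_pos  # tolerate a single flipped window
  expect_gte(r[2], r[1] - tol)
  expect_gte(r[3], r[2] - tol)
  expect_gte(r[3], r[1])
})

test_that("tidiers summarise fitted models", {
  bed <- small_bed()
  m <- ca_fit(bed$X, bed$y, quick_cfg(), seed = 6)
  g <- glance(m)
  expect_equal(g$n_features, ncol(bed$X))
  td <- tidy(m, newdata = bed$X[1:50, ])
  expect_equal(names(td), c("feature", "importance"))
  expect_error(tidy(m), "newdata")
})
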