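screen_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) abort("feature matrix must be numeric")
  if (any(!is.finite(X))) abort("feature matrix contains non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

check_binary_y <- function(y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  y
}

# row subsample used to keep importance fits cheap: arrest windows are rare
# and carry all the signal, so every positive is kept (up to half the cap)
# and only the majority class is downsampled
screen_rows <- function(y, cap, seed) {
  n <- length(y)
  if (n <= cap) return(seq_len(n))
  withr::with_seed(seed, {
    pos <- which(y == 1); neg <- which(y == 0)
    n_pos <- min(length(pos), ceiling(cap / 2))
    n_neg <- cap - n_pos
    sort(c(sample(pos, n_pos), sample(neg, min(n_neg, length(neg)))))
  })
}

xgb_importance <- function(X, y, config, seed, nrounds = NULL) {
  spw <- max(sum(y == 0), 1) / max(sum(y == 1), 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$screen_max_depth, eta = 0.3,
                  scale_pos_weight = spw, tree_method = "hist",
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds %||% config$screen_nrounds,
    verbose = 0
  )
  imp <- xgboost::xgb.importance(model = booster)
  out <- setNames(rep(0, ncol(X)), colnames(X))
  out[imp$Feature] <- imp$Gain
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recursive feature elimination
#'
#' Repeatedly fits a class-weighted gradient-boosted model and drops the
#' lowest-importance `rfe_step` fraction of the surviving features until
#' exactly `n_keep` remain. Deterministic given `seed`.
#'
#' @param X numeric feature matrix (or tibble) with column names.
#' @param y binary labels (both classes required).
#' @param n_keep number of features to retain.
#' @param config an [arrest_config()] (boosting and subsampling settings).
#' @param seed integer seed.
#' @return Character vector of retained feature names.
#' @export
rfe_select <- function(X, y, n_keep, config = arrest_config(), seed = 1L) {
  config <- as_arrest_config(config)
  X <- screen_matrix(X)
  n_keep <- as.integer(n_keep)
  if (n_keep <= 0) return(character(0))
  if (n_keep >= ncol(X)) return(colnames(X))
  y <- check_binary_y(y)
  rows <- screen_rows(y, config$screen_row_cap, seed)
  Xs <- X[rows, , drop = FALSE]
  ys <- y[rows]
  active <- colnames(X)
  it <- 0L
  while (length(active) > n_keep) {
    it <- it + 1L
    imp <- xgb_importance(Xs[, active, drop = FALSE], ys, config,
                          seed = seed + it)
    drop_n <- min(max(1L, ceiling(config$rfe_step * length(active))),
                  length(active) - n_keep)
    active <- names(sort(imp, decreasing = TRUE))[seq_len(length(active) - drop_n)]
  }
  active
}

#' Shadow-feature relevance screening
#'
#' A Boruta-style all-relevant screen: each iteration shuffles every column
#' into a "shadow" copy, fits the importance model on real plus shadow
#' features, and counts a hit when a real feature beats the best shadow.
#' Features whose hit counts are binomially significantly above (below)
#' chance — with a Bonferroni-adjusted two-sided `boruta_alpha` — are
#' confirmed (rejected); features still tentative after `boruta_max_runs`
#' iterations are resolved by comparing their median importance with the
#' median best-shadow importance.
#'
#' @inheritParams rfe_select
#' @return Character vector of confirmed feature names.
#' @export
boruta_select <- function(X, y, config = arrest_config(), seed = 1L) {
  config <- as_arrest_config(config)
  X <- screen_matrix(X)
  y <- check_binary_y(y)
  rows <- screen_rows(y, config$screen_row_cap, seed)
  Xs <- X[rows, , drop = FALSE]
  ys <- y[rows]
  p <- ncol(Xs)
  feat <- colnames(Xs)
  status <- setNames(rep("tentative", p), feat)
  hits <- setNames(integer(p), feat)
  runs <- 0L
  imp_hist <- matrix(NA_real_, config$boruta_max_runs, p,
                     dimnames = list(NULL, feat))
  shadow_hist <- rep(NA_real_, config$boruta_max_runs)
  alpha <- config$boruta_alpha / p  # Bonferroni over the schema

  withr::with_seed(seed, {
    while (runs < config$boruta_max_runs && any(status == "tentative")) {
      runs <- runs + 1L
      active <- feat[status != "rejected"]
      shadow <- apply(Xs[, active, drop = FALSE], 2, sample)
      colnames(shadow) <- paste0(".shadow.", active)
      # importance is aggregated over many runs, so each fit can be shallow
      imp <- xgb_importance(cbind(Xs[, active, drop = FALSE], shadow), ys,
                            config, seed = seed + runs, nrounds = 10L)
      shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
      real_imp <- imp[active]
      imp_hist[runs, active] <- real_imp
      shadow_hist[runs] <- shadow_max
      hits[active] <- hits[active] + (real_imp > shadow_max)
      tent <- feat[status == "tentative"]
      p_up <- stats::pbinom(hits[tent] - 1L, runs, 0.5, lower.tail = FALSE)
      p_dn <- stats::pbinom(hits[tent], runs, 0.5)
      status[tent[p_up < alpha / 2]] <- "confirmed"
      status[tent[p_dn < alpha / 2]] <- "rejected"
    }
  })
  tent <- feat[status == "tentative"]
  if (length(tent)) {
    med_shadow <- stats::median(shadow_hist, na.rm = TRUE)
    med_imp <- apply(imp_hist[, tent, drop = FALSE], 2, stats::median, na.rm = TRUE)
    status[tent[med_imp > med_shadow]] <- "confirmed"
    status[tent[med_imp <= med_shadow]] <- "rejected"
  }
  names(status)[status == "confirmed"]
}

#' Combine screening methods by majority vote
#'
#' Each screening method casts one vote for every feature it selected; a
#' feature enters the final set when its vote count reaches `threshold`
#' (default 2 — with two voters, majority means unanimity).
#'
#' @param rfe_set,boruta_set character vectors of selected feature names.
#' @param schema full candidate feature name vector.
#' @param threshold votes needed for selection (1 or 2).
#' @return A `screening_result`: tibble `feature`, `vote_rfe`, `vote_boruta`,
#'   `votes`, `selected`.
#' @export
ensemble_vote <- function(rfe_set, boruta_set, schema, threshold = 2L) {
  stray <- setdiff(c(rfe_set, boruta_set), schema)
  if (length(stray)) {
    abort(paste0("selected feature(s) outside the schema: ",
                 paste(utils::head(stray, 3), collapse = ", ")))
  }
  out <- tibble(
    feature = schema,
    vote_rfe = as.integer(schema %in% rfe_set),
    vote_boruta = as.integer(schema %in% boruta_set)
  ) %>%
    mutate(votes = .data$vote_rfe + .data$vote_boruta,
           selected = .data$votes >= threshold)
  class(out) <- c("screening_result", class(out))
  out
}

#' @export
tidy.screening_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Run the full ensemble screen
#'
#' Convenience wrapper: recursive elimination to `n_keep_frac` of the
#' candidates, the shadow-feature screen, then the majority vote. Falls back
#' to the recursive-elimination set when the vote selects nothing.
#'
#' @inheritParams rfe_select
#' @return A `screening_result` (see [ensemble_vote()]); the selected names
#'   are in `attr(., "selected")`.
#' @export
screen_features <- function(X, y, config = arrest_config(), seed = 1L) {
  config <- as_arrest_config(config)
  X <- screen_matrix(X)
  n_keep <- max(1L, round(config$n_keep_frac * ncol(X)))
  rfe <- rfe_select(X, y, n_keep, config, seed)
  bor <- boruta_select(X, y, config, seed)
  res <- ensemble_vote(rfe, bor, colnames(X), config$vote_threshold)
  selected <- res$feature[res$selected]
  if (!length(selected)) selected <- rfe
  attr(res, "selected") <- selected
  res
}
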