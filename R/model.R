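#' Fit the cost-sensitive arrest classifier
#'
#' Trains the attentive tabular classifier (default backend): sequential
#' decision steps with input-dependent sparse feature masks, a class-weighted
#' cross-entropy loss that penalizes missed arrest windows `class_weight_ca`
#' times more than false alarms, an entropy sparsity regularizer, Adam
#' optimization at `learning_rate`, and validation-based early stopping. The
#' `"xgboost"` backend fits a class-weighted gradient-boosted model behind the
#' identical fit/predict/explain contract and is useful when speed matters
#' more than per-step masks. Training is deterministic given `seed` (and a
#' fixed BLAS thread count).
#'
#' @param X numeric feature matrix or tibble (screened features only).
#' @param y binary labels, both classes present.
#' @param config an [arrest_config()]; the relevant keys are `backend`,
#'   `class_weight_ca`, `learning_rate`, `n_steps`, `width`, `relaxation`,
#'   `sparsity`, `epochs`, `patience`, `batch_size`, `val_frac`, and the
#'   `xgb_*` group.
#' @param seed integer seed.
#' @param groups optional grouping vector (typically `patient_id`) aligned to
#'   the rows of `X`; when given, the attentive backend's early-stopping
#'   validation split is made at group level so the stopping criterion
#'   measures generalization to unseen patients.
#' @return A `ca_model` object.
#' @export
#' @examples
#' bed <- planted_feature_bed(n = 300, n_informative = 3, n_noise = 5, seed = 3)
#' m <- ca_fit(bed$X, bed$y, arrest_config(epochs = 20, class_weight_ca = 3))
#' head(predict(m, bed$X))
ca_fit <- function(X, y, config = arrest_config(), seed = config$seed,
                   groups = NULL) {
  config <- as_arrest_config(config)
  if (is.data.frame(X)) X <- as.matrix(X)
  nan_cols <- colnames(X)[colSums(!is.finite(X)) > 0]
  if (length(nan_cols)) {
    abort(paste0("non-finite values in feature(s): ",
                 paste(utils::head(nan_cols, 5), collapse = ", ")))
  }
  X <- screen_matrix(X)
  y <- check_binary_y(y)
  seed <- as.integer(seed)
  fit <- switch(config$backend,
    attentive = fit_attentive(X, y, config, seed, groups = groups),
    xgboost = fit_xgb_backend(X, y, config, seed),
    abort(paste0("unknown backend: ", config$backend))
  )
  structure(list(backend = config$backend, schema = colnames(X),
                 config = config, seed = seed, fit = fit,
                 n_train = nrow(X)),
            class = "ca_model")
}

fit_xgb_backend <- function(X, y, config, seed) {
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$xgb_max_depth, eta = config$xgb_eta,
                  scale_pos_weight = config$class_weight_ca,
                  tree_method = "hist", nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = config$xgb_nrounds,
    verbose = 0
  )
  list(booster = booster)
}

align_schema <- function(object, newdata) {
  X <- screen_matrix(newdata)
  missing <- setdiff(object$schema, colnames(X))
  extra <- setdiff(colnames(X), object$schema)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "feature schema mismatch",
      if (length(missing)) paste0("; missing: ",
                                  paste(utils::head(missing, 5), collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ",
                                paste(utils::head(extra, 5), collapse = ", "))
    ))
  }
  X[, object$schema, drop = FALSE]
}

#' Predict arrest-risk probabilities
#'
#' Columns of `newdata` are aligned to the training schema by name, so column
#' order is irrelevant; missing or extra features raise an error naming them.
#'
#' @param object a `ca_model`.
#' @param newdata feature matrix or tibble.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ca_model <- function(object, newdata, ...) {
  X <- align_schema(object, newdata)
  switch(object$backend,
    attentive = predict_attentive(object$fit, X),
    xgboost = as.numeric(stats::predict(object$fit$booster, X))
  )
}

#' Decision-mask attributions
#'
#' Returns the per-step attentive masks (nonnegative, each row summing to 1),
#' the per-sample aggregate importance (step masks weighted by each step's
#' nonnegative decision contribution, renormalized to sum to 1 per sample),
#' and the global importance (mean aggregate importance per feature). For the
#' xgboost backend the single "step" mask is the normalized absolute
#' per-sample SHAP contribution.
#'
#' @param model a `ca_model`.
#' @param newdata feature matrix or tibble.
#' @return A `ca_explanation` list: `masks` (list of n-by-p matrices, one per
#'   step), `importance` (n-by-p), `global` (tibble `feature`, `importance`,
#'   sorted descending).
#' @export
ca_explain <- function(model, newdata) {
  X <- align_schema(model, newdata)
  ex <- switch(model$backend,
    attentive = explain_attentive(model$fit, X),
    xgboost = {
      contrib <- stats::predict(model$fit$booster, X, predcontrib = TRUE)
      contrib <- abs(contrib[, colnames(X), drop = FALSE])
      rs <- rowSums(contrib)
      zero <- rs <= 0
      contrib[!zero, ] <- contrib[!zero, , drop = FALSE] / rs[!zero]
      if (any(zero)) contrib[zero, ] <- 1 / ncol(X)
      list(masks = list(contrib), importance = contrib)
    }
  )
  gl <- colMeans(ex$importance)
  ex$global <- tibble(feature = names(gl), importance = as.numeric(gl)) %>%
    arrange(dplyr::desc(.data$importance), .data$feature)
  class(ex) <- "ca_explanation"
  ex
}

#' @export
print.ca_model <- function(x, ...) {
  cat("<ca_model> backend:", x$backend, "| features:", length(x$schema),
      "| trained on", x$n_train, "windows\n")
  if (x$backend == "attentive") {
    cat("  best epoch:", x$fit$best_epoch, "of", x$fit$epochs_run,
        "| validation loss:", signif(x$fit$val_loss, 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.ca_model <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    abort("tidy.ca_model needs `newdata` to compute mask attributions")
  }
  ca_explain(x, newdata)$global
}

#' @export
glance.ca_model <- function(x, ...) {
  tibble(backend = x$backend, n_features = length(x$schema),
         n_train = x$n_train,
         class_weight_ca = x$config$class_weight_ca,
         best_epoch = if (x$backend == "attentive") x$fit$best_epoch else NA_integer_)
}

#' Class-weighted cross-entropy
#'
#' The training criterion of the classifier, exposed for inspection: with unit
#' weights it reduces to ordinary binary cross-entropy.
#'
#' @param prob predicted probabilities; @param y binary labels;
#'   @param weights per-observation weights (e.g. 100 for arrest windows).
#' @return Mean weighted cross-entropy (normalized by the weight sum).
#' @export
weighted_cross_entropy <- function(prob, y, weights = rep(1, length(y))) {
  eps <- 1e-8
  sum(weights * (-(y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))) /
    sum(weights)
}
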