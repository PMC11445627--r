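as_importance_matrix <- function(importance) {
  if (inherits(importance, "ca_explanation")) importance <- importance$importance
  if (is.data.frame(importance)) importance <- as.matrix(importance)
  if (is.null(colnames(importance))) abort("importance matrix needs feature names")
  importance
}

#' Global importance report
#'
#' Mean per-sample mask importance per feature, ranked descending (ties broken
#' lexicographically by name), truncated to the top `k` (default 25).
#'
#' @param importance a `ca_explanation` from [ca_explain()] or an
#'   n-by-features importance matrix.
#' @param k number of features to report.
#' @return A tibble `rank`, `feature`, `importance`.
#' @export
global_report <- function(importance, k = 25L) {
  imp <- as_importance_matrix(importance)
  if (k > ncol(imp)) {
    warn(paste0("k = ", k, " exceeds the ", ncol(imp),
                "-feature schema; truncating"))
    k <- ncol(imp)
  }
  means <- colMeans(imp)
  ord <- order(-means, names(means))
  tibble(rank = seq_len(k),
         feature = names(means)[ord][seq_len(k)],
         importance = as.numeric(means[ord])[seq_len(k)])
}

#' Hour-by-channel mask heatmap data
#'
#' Averages mask importance over samples for the per-hour time-step features
#' (`<CHANNEL>_<h>h`), giving the temporal attribution matrix behind the
#' heatmap: which lookback hours of which channels the model attends to.
#' Multiresolution and Gini features carry no single hour and are excluded.
#'
#' @inheritParams global_report
#' @return A tibble `hour` (1-based lookback hour), `channel`, `importance`,
#'   ordered by hour; values are nonnegative.
#' @export
temporal_heatmap_data <- function(importance) {
  imp <- as_importance_matrix(importance)
  nm <- colnames(imp)
  is_ts <- grepl("_\\d+h$", nm) & !startsWith(nm, "Gini_")
  if (!any(is_ts)) abort("no per-hour time-step features in the importance matrix")
  nm_ts <- nm[is_ts]
  means <- colMeans(imp[, is_ts, drop = FALSE])
  tibble(
    hour = as.integer(sub("^.*_(\\d+)h$", "\\1", nm_ts)),
    channel = sub("_\\d+h$", "", nm_ts),
    importance = as.numeric(means)
  ) %>% arrange(.data$hour, .data$channel)
}

#' Feature-importance differences between outcome groups
#'
#' Two-sided Welch t test per feature comparing mask importances of arrest
#' versus non-arrest windows, with Benjamini-Hochberg false-discovery-rate
#' adjustment; features constant in both groups get p = 1.
#'
#' @inheritParams global_report
#' @param labels binary window labels aligned to the importance rows.
#' @param alpha significance level on the adjusted p-values.
#' @return A tibble `feature`, `estimate` (mean difference, arrest minus
#'   non-arrest), `statistic`, `p.value`, `p.adjusted`, `significant`.
#' @export
group_difference <- function(importance, labels, alpha = 0.05) {
  imp <- as_importance_matrix(importance)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(imp))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < 2 || n0 < 2) abort("each group needs at least 2 samples")
  A <- imp[labels == 1, , drop = FALSE]
  B <- imp[labels == 0, , drop = FALSE]
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  se2 <- vA / n1 + vB / n0
  stat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / n1)^2 / (n1 - 1) + (vB / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # degenerate features: no variance anywhere
  flat <- se2 == 0
  stat[flat] <- 0
  p[flat & (mA - mB) == 0] <- 1
  p[flat & (mA - mB) != 0] <- 0
  p[is.na(p)] <- 1
  tibble(feature = colnames(imp), estimate = mA - mB,
         statistic = stat, p.value = p,
         p.adjusted = stats::p.adjust(p, method = "BH")) %>%
    mutate(significant = .data$p.adjusted < alpha) %>%
    arrange(.data$p.adjusted, .data$feature)
}
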