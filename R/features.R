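stat_labels <- c(mean = "Mean", median = "Median", min = "Min", max = "Max",
                 sd = "SD", skewness = "Skewness")

#' Materialize lookback windows as a dense matrix
#'
#' Slices the channel grid into one row per window, laid out channel-major:
#' for each channel, the `window_hours` hourly values of the lookback
#' `[t_end - window_hours, t_end)`, oldest first. Hour naming inside the
#' window is 1-based, so `HR_8h` is the value at lookback hour 8 (the 7th
#' 0-based offset).
#'
#' @param channel_grid long tibble from [preprocess_channels()].
#' @param windows window index from [label_windows()].
#' @param window_hours lookback length in hours.
#' @return A list with `mat` (numeric matrix windows x (channels *
#'   window_hours)), `channels` (channel order) and `windows` (the index,
#'   aligned to rows).
#' @export
extract_window_matrix <- function(channel_grid, windows, window_hours = 12L) {
  chans <- unique(channel_grid$channel)
  if (!length(chans)) abort("channel grid has no channels")
  by_stay <- split(seq_len(nrow(windows)), windows$stay_id)
  grid_split <- split(channel_grid, channel_grid$stay_id)
  mat <- matrix(NA_real_, nrow(windows), length(chans) * window_hours)
  for (sid in names(by_stay)) {
    rows <- by_stay[[sid]]
    g <- grid_split[[sid]]
    if (is.null(g)) abort(paste0("no grid rows for stay ", sid))
    n_hours <- max(g$hour) + 1L
    # g is ordered (channel, hour); rebuild defensively if not
    if (nrow(g) != n_hours * length(chans)) {
      abort(paste0("ragged channel grid for stay ", sid))
    }
    M <- matrix(g$value[order(match(g$channel, chans), g$hour)],
                nrow = n_hours, ncol = length(chans))
    t_end <- windows$t_end[rows]
    if (any(t_end < window_hours) || any(t_end > n_hours)) {
      abort(paste0("window t_end outside stay grid for stay ", sid))
    }
    idx <- outer(t_end - window_hours + 1L, 0:(window_hours - 1L), "+")
    for (c in seq_along(chans)) {
      block <- matrix(M[as.vector(idx), c], length(rows), window_hours)
      mat[rows, (c - 1L) * window_hours + seq_len(window_hours)] <- block
    }
  }
  colnames(mat) <- as.vector(t(outer(chans, seq_len(window_hours),
                                     function(ch, h) paste0(ch, "_", h, "h"))))
  list(mat = mat, channels = chans, windows = windows,
       window_hours = as.integer(window_hours))
}

#' Per-hour time-step features
#'
#' One feature per channel per lookback hour, named `<CHANNEL>_<h>h` with
#' 1-based hour `h`. For the default 13 channels and a 12-hour window this is
#' 156 features.
#'
#' @param wm window matrix from [extract_window_matrix()].
#' @return A numeric matrix, one row per window.
#' @export
timestep_features <- function(wm) {
  wm$mat
}

#' Multiresolution statistical features
#'
#' For every channel and every segment of the plan (default: 4-hour tiles
#' 1-4, 5-8, 9-12; 6-hour tiles 1-6, 7-12; and the full window 1-12) the
#' statistic set is computed over the segment's hourly values: mean, median,
#' min, max, population SD and adjusted Fisher-Pearson skewness (0 for a
#' constant segment). Names follow `<CHANNEL>_<a>_<b>h_<Stat>`. Defaults give
#' 13 channels x 6 segments x 6 statistics = 468 features.
#'
#' @param wm window matrix from [extract_window_matrix()].
#' @param segment_plan list of `c(first_hour, last_hour)` pairs (1-based,
#'   inclusive).
#' @param stats statistic names, a subset of
#'   mean/median/min/max/sd/skewness.
#' @return A numeric matrix, one row per window.
#' @export
multiresolution_features <- function(wm,
                                     segment_plan = arrest_config()$segment_plan,
                                     stats = arrest_config()$stats) {
  W <- wm$window_hours
  bad <- !stats %in% names(stat_labels)
  if (any(bad)) abort(paste0("unknown statistic(s): ",
                             paste(stats[bad], collapse = ", ")))
  for (seg in segment_plan) {
    if (length(seg) != 2 || seg[1] < 1 || seg[2] > W || seg[1] > seg[2]) {
      abort(paste0("segment outside [1, ", W, "]: ",
                   paste(seg, collapse = "-")))
    }
  }
  stat_idx <- match(stats, names(stat_labels))
  pieces <- vector("list", length(wm$channels) * length(segment_plan))
  k <- 0
  for (c in seq_along(wm$channels)) {
    base <- (c - 1L) * W
    for (seg in segment_plan) {
      k <- k + 1
      block <- wm$mat[, base + seg[1]:seg[2], drop = FALSE]
      st <- row_stats(block)[, stat_idx, drop = FALSE]
      colnames(st) <- paste0(wm$channels[c], "_", seg[1], "_", seg[2], "h_",
                             stat_labels[stats])
      pieces[[k]] <- st
    }
  }
  do.call(cbind, pieces)
}

#' Gini-dispersion features
#'
#' Per channel, the Gini coefficient `G` of the window's hourly values
#' (pairwise mean absolute difference scaled by twice the mean; 0 when the
#' mean is 0) is folded into `GV = 1 - 2G / N_diff`, where `N_diff` is the
#' number of hourly intervals in the window (11 for 12 values). A stable
#' series gives `GV = 1`; a destabilizing spike lowers `GV` as `G` rises.
#' Names follow `Gini_<CHANNEL>_<W>h`.
#'
#' @param wm window matrix from [extract_window_matrix()].
#' @return A numeric matrix, one column per channel.
#' @export
gini_features <- function(wm) {
  W <- wm$window_hours
  n_diff <- W - 1L
  out <- vapply(seq_along(wm$channels), function(c) {
    block <- wm$mat[, (c - 1L) * W + seq_len(W), drop = FALSE]
    1 - 2 * row_gini(block) / n_diff
  }, numeric(nrow(wm$mat)))
  out <- matrix(out, nrow = nrow(wm$mat))
  colnames(out) <- paste0("Gini_", wm$channels, "_", W, "h")
  out
}

#' Assemble the candidate feature matrix
#'
#' Concatenates the three fragments in fixed order — time-step,
#' multiresolution, Gini — and prefixes the window index columns, yielding the
#' canonical feature table (637 candidates under the default design).
#'
#' @param channel_grid long channel grid from [preprocess_channels()].
#' @param windows labeled window index from [label_windows()].
#' @param config an [arrest_config()].
#' @param cohort optional cohort tibble; when given, `patient_id` is carried
#'   into the output.
#' @return A tibble: `stay_id`, (`patient_id`,) `t_end`, `label`, then one
#'   column per feature.
#' @export
#' @examples
#' d <- synth_cohort(n_patients = 6, ca_fraction = 0.3, seed = 2)
#' ch <- preprocess_channels(d$observations, d$cohort)
#' w <- label_windows(d$cohort)
#' fm <- window_features(ch, w, cohort = d$cohort)
#' dim(fm)
window_features <- function(channel_grid, windows, config = arrest_config(),
                            cohort = NULL) {
  config <- as_arrest_config(config)
  wm <- extract_window_matrix(channel_grid, windows, config$window_hours)
  frags <- list(timestep_features(wm),
                multiresolution_features(wm, config$segment_plan, config$stats))
  if (isTRUE(config$gini)) frags <- c(frags, list(gini_features(wm)))
  X <- do.call(cbind, frags)
  if (anyDuplicated(colnames(X))) {
    abort("internal error: duplicate feature names in assembled matrix")
  }
  if (isTRUE(getOption("arrestwatch.verbose"))) {
    inform(paste0("window_features: ", ncol(X), " candidate features over ",
                  nrow(X), " windows"))
  }
  out <- bind_cols(wm$windows, as_tibble(X))
  if (!is.null(cohort)) {
    out <- out %>%
      left_join(select(cohort, "stay_id", "patient_id"), by = "stay_id") %>%
      select("stay_id", "patient_id", dplyr::everything())
  }
  out
}

#' Names of the feature schema implied by a configuration
#'
#' The schema is a pure function of the configuration (channel set, segment
#' plan, statistics, Gini toggle), never of the data.
#'
#' @param config an [arrest_config()].
#' @param channels channel order (default the shipped chart's 13 channels).
#' @return Character vector of feature names.
#' @export
feature_schema <- function(config = arrest_config(), channels = channel_order()) {
  config <- as_arrest_config(config)
  W <- config$window_hours
  ts <- as.vector(t(outer(channels, seq_len(W),
                          function(ch, h) paste0(ch, "_", h, "h"))))
  mr <- unlist(lapply(channels, function(ch) {
    unlist(lapply(config$segment_plan, function(seg) {
      paste0(ch, "_", seg[1], "_", seg[2], "h_", stat_labels[config$stats])
    }))
  }))
  gi <- if (isTRUE(config$gini)) paste0("Gini_", channels, "_", W, "h") else character(0)
  c(ts, mr, gi)
}

#' Split a feature table into matrix, labels and index
#' @param features tibble from [window_features()].
#' @return list with `X` (numeric matrix), `y` (integer labels), `index`
#'   (stay_id/patient_id/t_end columns).
#' @export
feature_parts <- function(features) {
  meta <- intersect(c("stay_id", "patient_id", "t_end", "label"), names(features))
  X <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  list(X = X,
       y = if ("label" %in% meta) as.integer(features$label) else NULL,
       index = features[, setdiff(meta, "label"), drop = FALSE])
}
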