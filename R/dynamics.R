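#' Bootstrap mean network activity
#'
#' Per iteration, resamples trials with replacement (cells are never
#' resampled) and averages the binary activity over cells and trials per
#' bin, giving a bootstrap distribution of the mean-network-activity time
#' course for one condition. Mean and percentile confidence band are
#' reported per bin; iteration curves are kept so distributions from
#' several animals can be pooled into one grand distribution
#' ([pool_network_summaries()]).
#'
#' @param raster A `spike_raster`.
#' @param trials Trial ids to include (the condition); default all.
#' @param n_iter Bootstrap iterations (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A `network_summary`: data frame with `time`, `mean`, `lo`,
#'   `hi`; iteration curves (n_iter x bins) in attribute `iterations`.
#' @export
bootstrap_mean_activity <- function(raster, trials = NULL, n_iter = 1000L,
                                    conf = 0.95, seed = NULL) {
  if (!inherits(raster, "spike_raster"))
    stop_validation("raster must be a spike_raster")
  all_ids <- raster$trial_ids
  if (is.null(all_ids)) all_ids <- seq_len(dim(raster$activity)[3])
  if (is.null(trials)) trials <- all_ids
  idx <- match(trials, all_ids)
  if (!length(idx) || anyNA(idx))
    stop_validation("condition contains no valid trials")
  # cells x bins x trials -> per-trial network mean per bin (bins x trials)
  trial_means <- apply(raster$activity[, , idx, drop = FALSE], c(2, 3), mean)
  trial_means <- matrix(trial_means, ncol = length(idx))
  with_seed(seed, {
    iters <- t(vapply(seq_len(n_iter), function(i) {
      take <- sample.int(length(idx), replace = TRUE)
      rowMeans(trial_means[, take, drop = FALSE])
    }, numeric(nrow(trial_means))))
    structure(
      data.frame(time = raster$times,
                 mean = colMeans(iters),
                 lo = apply(iters, 2, quantile, (1 - conf) / 2),
                 hi = apply(iters, 2, quantile, 1 - (1 - conf) / 2)),
      iterations = iters, n_iter = n_iter, conf = conf,
      class = c("network_summary", "data.frame"))
  })
}

#' Pool bootstrap summaries across animals
#'
#' Stacks the iteration curves of per-animal [bootstrap_mean_activity()]
#' summaries (same bin grid) into one grand distribution and recomputes
#' mean and percentile band.
#'
#' @param summaries List of `network_summary` objects.
#' @param conf Confidence level.
#' @return A `network_summary` over the pooled iterations.
#' @export
pool_network_summaries <- function(summaries, conf = 0.95) {
  iters <- do.call(rbind, lapply(summaries, attr, "iterations"))
  structure(
    data.frame(time = summaries[[1]]$time,
               mean = colMeans(iters),
               lo = apply(iters, 2, quantile, (1 - conf) / 2),
               hi = apply(iters, 2, quantile, 1 - (1 - conf) / 2)),
    iterations = iters, n_iter = nrow(iters), conf = conf,
    class = c("network_summary", "data.frame"))
}

#' Correlation of network activity with the stimulus indicator
#'
#' Pearson correlation between bootstrapped mean network activity and the
#' binary stimulus on/off indicator, pooled over all (iteration, bin)
#' pairs, with the analytic p-value.
#'
#' @param summary A `network_summary`.
#' @param indicator 0/1 vector on the same bin grid (see
#'   [stimulus_indicator()]).
#' @return List with `r` and `p`.
#' @export
stimulus_correlation <- function(summary, indicator) {
  iters <- attr(summary, "iterations")
  if (is.null(iters)) stop_validation("summary lacks iteration curves")
  if (length(indicator) != ncol(iters))
    stop_validation("indicator and activity are on different bin grids")
  y <- rep(as.numeric(indicator), each = nrow(iters))
  x <- as.numeric(iters)
  if (sd(x) == 0 || sd(y) == 0)
    stop_validation("zero-variance input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-cell peak activity times
#'
#' For each cell, the time of maximum trial-averaged activity within a
#' stated period; ties resolve to the earliest bin. The distribution of
#' these peak times across cells (and its CDF) indexes how the network's
#' activity is re-timed by learning.
#'
#' @param raster A `spike_raster`.
#' @param trials Trial ids defining the condition; default all.
#' @param period `c(start, end)` seconds within the trial horizon.
#' @return A `peak_time_dist`: data frame with `cell` and `peak_time`
#'   (bin onset, seconds); attribute `period`.
#' @export
peak_times <- function(raster, trials = NULL, period) {
  if (!inherits(raster, "spike_raster"))
    stop_validation("raster must be a spike_raster")
  if (length(period) != 2L || period[2] <= period[1])
    stop_validation("period must be c(start, end) with end > start")
  all_ids <- raster$trial_ids
  if (is.null(all_ids)) all_ids <- seq_len(dim(raster$activity)[3])
  if (is.null(trials)) trials <- all_ids
  idx <- match(trials, all_ids)
  if (!length(idx) || anyNA(idx)) stop_validation("no valid trials")
  bins <- which(raster$times + raster$bin_width / 2 >= period[1] &
                  raster$times + raster$bin_width / 2 < period[2])
  if (!length(bins)) stop_validation("period contains no raster bins")
  traces <- apply(raster$activity[, bins, idx, drop = FALSE], c(1, 2), mean)
  traces <- matrix(traces, ncol = length(bins))
  peak_bin <- apply(traces, 1, which.max)  # earliest on ties
  structure(data.frame(cell = seq_len(nrow(traces)),
                       peak_time = raster$times[bins][peak_bin]),
            period = period, class = c("peak_time_dist", "data.frame"))
}

#' Compare peak-time distributions (KS with Bonferroni)
#'
#' Two-sample Kolmogorov-Smirnov test per pair of peak-time distributions,
#' with the family alpha Bonferroni-divided by the number of pairs (six
#' pairwise comparisons give adjusted alpha 0.0083, three give 0.0167).
#' Exact p-values are used for samples under 30, the asymptotic
#' distribution otherwise.
#'
#' @param dists Named list of `peak_time_dist` objects (or numeric
#'   vectors of peak times).
#' @param pairs List of 2-vectors of names into `dists`; default all
#'   pairs.
#' @param family_alpha Family-wise level (default 0.05).
#' @return Data frame with `pair`, `D`, `p`, `alpha_adj`, `significant`.
#' @export
compare_peak_distributions <- function(dists, pairs = NULL,
                                       family_alpha = 0.05) {
  vals <- lapply(dists, function(d)
    if (is.data.frame(d)) d$peak_time else as.numeric(d))
  if (is.null(pairs)) {
    nm <- names(vals)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  keep <- vapply(pairs, function(pr)
    length(vals[[pr[1]]]) >= 2 && length(vals[[pr[2]]]) >= 2, logical(1))
  if (any(!keep)) message("skipping pairs with fewer than 2 samples")
  pairs <- pairs[keep]
  alpha_adj <- family_alpha / length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    exact <- min(length(a), length(b)) < 30
    kt <- suppressWarnings(ks.test(a, b, exact = exact))
    data.frame(pair = paste(pr, collapse = " vs "),
               D = unname(kt$statistic), p = kt$p.value,
               alpha_adj = alpha_adj,
               significant = kt$p.value < alpha_adj)
  })
  do.call(rbind, rows)
}

#' Order cells by peak activity time
#'
#' Returns the cell ordering used for time-sorted heatmaps: cells grouped
#' by the bin of their maximum mean activity, groups in ascending
#' peak-time order, ties within a group by cell index.
#'
#' @param traces Cells x bins matrix of mean activity traces.
#' @return Integer permutation of the cell indices.
#' @export
sort_by_peak_time <- function(traces) {
  traces <- as.matrix(traces)
  peak <- apply(traces, 1, which.max)
  order(peak, seq_len(nrow(traces)))
}

#' Outcome-conditioned neural trajectories (PCA)
#'
#' Averages each cell's activity over trials within each outcome, fits a
#' principal component analysis to the concatenated (outcome x bin)
#' observations (variables are cells; per-cell mean centering, no variance
#' scaling), and returns the first three component trajectories per
#' outcome plus the variance explained. A scalar divergence between two
#' outcomes — the mean Euclidean distance between their trajectories over
#' bins in the retained component space — is available via
#' [trajectory_divergence()].
#'
#' @param raster A `spike_raster`.
#' @param outcomes Labeled `trial_table` for the raster's trials.
#' @param n_components Components retained (default 3).
#' @param min_trials Outcomes with fewer trials are dropped with a message.
#' @return A `trajectory_set`: list with `trajectories` (named list of
#'   bins x components score matrices), `variance_explained` (percent, all
#'   components), `times`.
#' @export
outcome_trajectories <- function(raster, outcomes, n_components = 3L,
                                 min_trials = 2L) {
  if (!inherits(raster, "spike_raster"))
    stop_validation("raster must be a spike_raster")
  d <- dim(raster$activity)
  if (d[1] < 2L || d[2] < 2L)
    stop_validation("need at least 2 cells and 2 bins")
  all_ids <- raster$trial_ids
  if (is.null(all_ids)) all_ids <- seq_len(d[3])
  labs <- setdiff(unique(outcomes$outcome), "unlabeled")
  mats <- list()
  for (o in labs) {
    idx <- match(outcomes$trial_id[outcomes$outcome == o], all_ids)
    if (length(idx) < min_trials) {
      message("dropping outcome ", o, ": fewer than ", min_trials, " trials")
      next
    }
    m <- apply(raster$activity[, , idx, drop = FALSE], c(1, 2), mean)
    mats[[o]] <- t(matrix(m, nrow = d[1]))  # bins x cells
  }
  if (!length(mats)) stop_validation("no outcome has enough trials")
  x <- do.call(rbind, mats)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components)
    warning("input rank supports only ", k, " components")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  n_bins <- d[2]
  traj <- list()
  for (i in seq_along(mats)) {
    rows <- (i - 1L) * n_bins + seq_len(n_bins)
    traj[[names(mats)[i]]] <- scores[rows, , drop = FALSE]
  }
  structure(list(trajectories = traj, variance_explained = ve,
                 times = raster$times, n_components = k),
            class = "trajectory_set")
}

#' Divergence between two outcome trajectories
#'
#' Mean Euclidean distance between two trajectories of a
#' [outcome_trajectories()] fit, over time bins, in the retained
#' component space.
#'
#' @param trajset A `trajectory_set`.
#' @param a,b Outcome names.
#' @return Non-negative scalar.
#' @export
trajectory_divergence <- function(trajset, a, b) {
  if (!all(c(a, b) %in% names(trajset$trajectories)))
    stop_validation("unknown outcome name")
  ta <- trajset$trajectories[[a]]
  tb <- trajset$trajectories[[b]]
  mean(sqrt(rowSums((ta - tb)^2)))
}
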