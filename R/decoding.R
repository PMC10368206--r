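#' Bin events into per-time-bin feature matrices
#'
#' Converts lick trains or a spike raster into the per-bin feature matrices
#' consumed by the decoders. Licks become a single feature per bin (the
#' lick count in a 0.067 s window per trial); a raster contributes one
#' feature per cell (its binary value in that bin), with the 15 Hz raster
#' bins mapping one-to-one onto the decoding bins. The number of bins is
#' `floor(horizon / bin_width)`; a final partial bin is dropped.
#'
#' @param x A `lick_trains` or `spike_raster` object.
#' @param ... Passed to methods.
#' @return An object of class `binned_features`: list with `bins` (list of
#'   trials x features matrices, one per time bin), `times` (bin onsets,
#'   seconds), `bin_width`, `trial_ids`, `type`.
#' @export
bin_features <- function(x, ...) UseMethod("bin_features")

#' @param trial_ids Trials to include (and their row order); defaults to
#'   all trials present.
#' @param bin_width Bin width in seconds (default 0.067).
#' @param horizon Time covered, seconds; defaults to the object's horizon.
#' @rdname bin_features
#' @export
bin_features.lick_trains <- function(x, trial_ids = NULL, bin_width = 0.067,
                                     horizon = NULL, ...) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(horizon)) horizon <- attr(x, "horizon")
  if (is.null(horizon)) stop_validation("horizon is required")
  if (is.null(trial_ids)) trial_ids <- sort(unique(x$trial_id))
  n_bins <- floor(horizon / bin_width)
  counts <- bin_lick_counts(x, trial_ids, bin_width, n_bins)
  structure(list(
    bins = lapply(seq_len(n_bins), function(k) counts[, k, drop = FALSE]),
    times = (seq_len(n_bins) - 1) * bin_width,
    bin_width = bin_width,
    trial_ids = trial_ids,
    type = "licks"
  ), class = "binned_features")
}

#' @rdname bin_features
#' @export
bin_features.spike_raster <- function(x, trial_ids = NULL, horizon = NULL, ...) {
  all_ids <- x$trial_ids
  if (is.null(all_ids)) all_ids <- seq_len(dim(x$activity)[3])
  if (is.null(trial_ids)) trial_ids <- all_ids
  idx <- match(trial_ids, all_ids)
  if (anyNA(idx)) stop_validation("trial_ids absent from raster")
  keep <- seq_along(x$times)
  if (!is.null(horizon))
    keep <- which(x$times + x$bin_width <= horizon + 1e-9)
  structure(list(
    bins = lapply(keep, function(k) t(x$activity[, k, idx, drop = TRUE])),
    times = x$times[keep],
    bin_width = x$bin_width,
    trial_ids = trial_ids,
    type = "spikes"
  ), class = "binned_features")
}

# ---- internal SVM machinery ----------------------------------------------

# median pairwise-distance heuristic for the RBF kernel scale;
# NA when all rows coincide (degenerate bin)
median_heuristic_gamma <- function(x, max_rows = 80L) {
  if (nrow(x) > max_rows) x <- x[seq_len(max_rows), , drop = FALSE]
  d <- as.numeric(dist(x))
  d <- d[d > 0]
  if (!length(d)) return(NA_real_)
  1 / (2 * median(d)^2)
}

# stratified train-index sample: round(split * n_c) per class, clamped so
# both sides keep at least one trial per class
stratified_train <- function(y, split) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    n_tr <- min(max(1L, round(split * length(idx))), length(idx) - 1L)
    sample(idx, n_tr)
  }), use.names = FALSE)
}

# RBF decision values straight from the fitted model's support vectors,
# coefficients and offset; avoids predict.svm's data-frame overhead in the
# bootstrap loops. Sign convention: positive = first label in m$labels.
rbf_decision <- function(m, xte) {
  sv <- m$SV
  k <- exp(-m$gamma *
             (outer(rowSums(xte^2), rowSums(sv^2), `+`) -
                2 * tcrossprod(xte, sv)))
  drop(k %*% m$coefs) - m$rho
}

fit_predict_acc <- function(x, y, train, cost, gamma) {
  g <- if (is.null(gamma)) median_heuristic_gamma(x[train, , drop = FALSE]) else gamma
  if (is.na(g)) {
    # constant features: the machine cannot separate; score chance
    return(0.5)
  }
  m <- e1071::svm(x[train, , drop = FALSE], y[train], kernel = "radial",
                  gamma = g, cost = cost, scale = FALSE)
  pred <- levels(y)[m$labels[(rbf_decision(m, x[-train, , drop = FALSE]) < 0) + 1L]]
  mean(pred == y[-train])
}

check_labels <- function(labels, n_trials) {
  labels <- factor(labels)
  if (length(labels) != n_trials)
    stop_validation("labels must match the number of trials")
  if (nlevels(droplevels(labels)) < 2L)
    stop_validation("both classes must be present")
  droplevels(labels)
}

# accuracy distribution for one bin: n_machines resampled 80/20 splits
bin_accuracies <- function(x, labels, n_machines, split, cost, gamma,
                           shuffle = FALSE) {
  if (is.na(median_heuristic_gamma(x)))
    return(list(accs = rep(0.5, n_machines), degenerate = TRUE))
  accs <- vapply(seq_len(n_machines), function(m) {
    y <- if (shuffle) sample(labels) else labels
    train <- stratified_train(y, split)
    fit_predict_acc(x, y, train, cost, gamma)
  }, numeric(1))
  list(accs = accs, degenerate = FALSE)
}

curve_from_accs <- function(accs, times, conf, n_machines, shuffled) {
  structure(
    data.frame(time = times,
               mean_acc = colMeans(accs),
               lo = apply(accs, 2, quantile, (1 - conf) / 2),
               hi = apply(accs, 2, quantile, 1 - (1 - conf) / 2)),
    accs = accs, n_machines = n_machines, conf = conf, shuffled = shuffled,
    class = c("decoding_curve", "data.frame")
  )
}

#' Time-resolved bootstrapped SVM decoding
#'
#' For each time bin, trains `n_machines` support-vector machines with an
#' RBF kernel, each on a freshly resampled stratified 80/20 train/test
#' split of the trials, and records the held-out accuracy. The resulting
#' per-bin accuracy distribution localizes *when* in the trial the
#' features discriminate the two classes. Bins whose features are
#' identical across all trials (e.g., lick bins before any licking) are
#' recorded at chance (0.5) with a warning.
#'
#' @param features A [bin_features()] result.
#' @param labels Two-class labels, one per trial (e.g., stimulus type or
#'   trial outcome).
#' @param n_machines Machines per bin. The reference analysis uses 10000
#'   for the single-feature lick predictor and 1000 for population
#'   predictors; smaller values trade CI resolution for runtime without
#'   biasing the mean.
#' @param split Training fraction of each resampled split (default 0.8).
#' @param cost,gamma RBF hyperparameters; `gamma = NULL` uses the median
#'   pairwise-distance heuristic per bin (see [tune_hyperparameters()] for
#'   tuned values).
#' @param conf Confidence level of the percentile band (default 0.95).
#' @param seed Integer seed; the full curve is reproducible.
#' @return A `decoding_curve`: data frame with `time`, `mean_acc`, `lo`,
#'   `hi`, carrying the machines x bins accuracy matrix in attribute
#'   `accs`.
#' @export
bootstrap_svm_curve <- function(features, labels, n_machines = 1000L,
                                split = 0.8, cost = 1, gamma = NULL,
                                conf = 0.95, seed = NULL) {
  if (!inherits(features, "binned_features"))
    stop_validation("features must come from bin_features()")
  if (n_machines < 1L) stop_validation("n_machines must be >= 1")
  labels <- check_labels(labels, length(features$trial_ids))
  with_seed(seed, {
    res <- lapply(features$bins, bin_accuracies, labels = labels,
                  n_machines = n_machines, split = split, cost = cost,
                  gamma = gamma, shuffle = FALSE)
    if (any(vapply(res, `[[`, logical(1), "degenerate")))
      warning("degenerate (constant-feature) bins recorded at chance accuracy 0.5")
    accs <- vapply(res, `[[`, numeric(n_machines), "accs")
    accs <- matrix(accs, nrow = n_machines)
    curve_from_accs(accs, features$times, conf, n_machines, shuffled = FALSE)
  })
}

#' Shuffled-label control curve
#'
#' Same machinery as [bootstrap_svm_curve()], but every machine sees an
#' independently permuted copy of the labels. The resulting band is the
#' chance reference against which decoding curves are judged.
#'
#' @inheritParams bootstrap_svm_curve
#' @return A `decoding_curve` with attribute `shuffled = TRUE`.
#' @export
shuffled_control <- function(features, labels, n_machines = 1000L,
                             split = 0.8, cost = 1, gamma = NULL,
                             conf = 0.95, seed = NULL) {
  if (!inherits(features, "binned_features"))
    stop_validation("features must come from bin_features()")
  labels <- check_labels(labels, length(features$trial_ids))
  with_seed(seed, {
    res <- lapply(features$bins, bin_accuracies, labels = labels,
                  n_machines = n_machines, split = split, cost = cost,
                  gamma = gamma, shuffle = TRUE)
    accs <- matrix(vapply(res, `[[`, numeric(n_machines), "accs"),
                   nrow = n_machines)
    curve_from_accs(accs, features$times, conf, n_machines, shuffled = TRUE)
  })
}

#' Tune RBF hyperparameters by cross-validated search
#'
#' Searches box constraint (cost) and kernel scale (gamma) over a
#' log-scaled space, scoring each candidate by stratified k-fold
#' cross-validated accuracy. The first candidate evaluated is always the
#' default pair (cost 1, median-heuristic gamma), so a budget of one
#' returns the defaults. Used for full-network neural decoding; the
#' single-feature lick predictor is run untuned.
#'
#' @param x Feature matrix (trials x features) for the bin or interval
#'   being tuned.
#' @param labels Two-class labels.
#' @param folds Number of CV folds (default 5).
#' @param budget Number of candidate pairs evaluated.
#' @param seed Integer seed for the candidate draw and fold assignment.
#' @return List with `cost`, `gamma`, `cv_accuracy`, and the evaluated
#'   candidate table `search`.
#' @export
tune_hyperparameters <- function(x, labels, folds = 5L, budget = 20L,
                                 seed = NULL) {
  labels <- check_labels(labels, nrow(x))
  g0 <- median_heuristic_gamma(x)
  if (is.na(g0)) g0 <- 1 / max(1, ncol(x))
  counts <- table(labels)
  if (min(counts) < folds) {
    warning("too few trials per class for ", folds,
            "-fold CV; returning default hyperparameters")
    return(list(cost = 1, gamma = g0, cv_accuracy = NA_real_,
                search = NULL))
  }
  with_seed(seed, {
    fold_id <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    cand <- data.frame(
      cost = c(1, 10^runif(budget - 1, -2, 3)),
      gamma = c(g0, g0 * 10^runif(budget - 1, -2, 2))
    )[seq_len(budget), , drop = FALSE]
    cand$cv_accuracy <- vapply(seq_len(nrow(cand)), function(i) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- which(fold_id != f)
        m <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                        kernel = "radial", gamma = cand$gamma[i],
                        cost = cand$cost[i], scale = FALSE)
        mean(predict(m, x[-tr, , drop = FALSE]) == labels[-tr])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cand$cv_accuracy)
    list(cost = cand$cost[best], gamma = cand$gamma[best],
         cv_accuracy = cand$cv_accuracy[best], search = cand)
  })
}

# forward sequential selection of k features maximizing held-out accuracy
# on an internal stratified split of the training trials. Ties are broken
# at random: with discrete features exact ties are pervasive, and a
# deterministic rule would turn selection counts into a position artifact.
forward_select <- function(x, y, train, k, cost) {
  inner_train <- train[stratified_train(y[train], 0.5)]
  inner_val <- setdiff(train, inner_train)
  selected <- integer(0)
  remaining <- seq_len(ncol(x))
  # zero-variance features carry no information and are never preferred
  const_col <- apply(x, 2, function(col) all(col == col[1]))
  for (step in seq_len(k)) {
    scores <- vapply(remaining, function(j) {
      if (const_col[j]) return(-Inf)
      cols <- c(selected, j)
      xs <- x[, cols, drop = FALSE]
      # candidate fits use the 1/dim kernel-scale default for speed; the
      # final machine is fit with the median heuristic
      m <- e1071::svm(xs[inner_train, , drop = FALSE], y[inner_train],
                      kernel = "radial", gamma = 1 / length(cols),
                      cost = cost, scale = FALSE)
      pred <- levels(y)[m$labels[(rbf_decision(m, xs[inner_val, , drop = FALSE]) < 0) + 1L]]
      mean(pred == y[inner_val])
    }, numeric(1))
    top <- which(scores == max(scores))
    if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
    pick <- remaining[top]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Decoding with forward sequential selection of k cells
#'
#' Per time bin and machine: draw a stratified 80/20 split, forward-select
#' `k` cells on the training trials (each addition scored by held-out
#' accuracy on an internal split), train the final k-cell machine, and
#' record its test accuracy together with which cells were selected. The
#' selection map reports, per bin and cell, the number of selections as a
#' fraction of the `k * n_machines` possible selection slots — when
#' `k = n_cells` every cell is selected in every machine and each accounts
#' for `1/k` of the slots.
#'
#' @inheritParams bootstrap_svm_curve
#' @param k Number of cells selected per machine; at most the number of
#'   cells.
#' @return List with `curve` (a `decoding_curve`) and `selection_map`
#'   (bins x cells matrix of selection fractions).
#' @export
kcell_selection_curve <- function(features, labels, k, n_machines = 1000L,
                                  split = 0.8, cost = 1, conf = 0.95,
                                  seed = NULL) {
  if (!inherits(features, "binned_features") ||
      !identical(features$type, "spikes"))
    stop_validation("features must be binned spike-raster features")
  n_feat <- ncol(features$bins[[1]])
  if (k > n_feat) stop_validation("k exceeds the number of cells (", n_feat, ")")
  labels <- check_labels(labels, length(features$trial_ids))
  with_seed(seed, {
    n_bins <- length(features$bins)
    accs <- matrix(0.5, n_machines, n_bins)
    counts <- matrix(0L, n_bins, n_feat)
    for (b in seq_len(n_bins)) {
      x <- features$bins[[b]]
      if (is.na(median_heuristic_gamma(x))) next
      for (m in seq_len(n_machines)) {
        train <- stratified_train(labels, split)
        sel <- forward_select(x, labels, train, k, cost)
        counts[b, sel] <- counts[b, sel] + 1L
        accs[m, b] <- fit_predict_acc(x[, sel, drop = FALSE], labels,
                                      train, cost, gamma = NULL)
      }
    }
    list(curve = curve_from_accs(accs, features$times, conf, n_machines,
                                 shuffled = FALSE),
         selection_map = counts / (k * n_machines))
  })
}

#' Pairwise trial-outcome decoding
#'
#' Runs [bootstrap_svm_curve()] plus its shuffled control for each outcome
#' pair (by default Hit vs CR, Hit vs FA, CR vs FA; Miss is omitted for
#' its small sample size). Pairs with an empty class are skipped with a
#' message.
#'
#' @param raster A `spike_raster`.
#' @param outcomes Labeled `trial_table` matching the raster's trials.
#' @param pairs List of 2-vectors of outcome labels.
#' @param horizon Optional time limit on the decoded bins, seconds.
#' @inheritParams bootstrap_svm_curve
#' @return Named list (e.g., `"Hit_vs_CR"`) of lists with elements `curve`
#'   and `control`.
#' @export
pairwise_outcome_decoding <- function(raster, outcomes,
                                      pairs = list(c("Hit", "CR"),
                                                   c("Hit", "FA"),
                                                   c("CR", "FA")),
                                      n_machines = 1000L, horizon = NULL,
                                      cost = 1, gamma = NULL, conf = 0.95,
                                      seed = NULL) {
  out <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    ids <- outcomes$trial_id[outcomes$outcome %in% pr]
    lab <- outcomes$outcome[outcomes$outcome %in% pr]
    nm <- paste(pr, collapse = "_vs_")
    if (length(unique(lab)) < 2L) {
      message("skipping ", nm, ": a class is empty")
      next
    }
    feats <- bin_features(raster, trial_ids = ids, horizon = horizon)
    out[[nm]] <- list(
      curve = bootstrap_svm_curve(feats, lab, n_machines = n_machines,
                                  cost = cost, gamma = gamma, conf = conf,
                                  seed = child_seed(seed, 2L * i)),
      control = shuffled_control(feats, lab, n_machines = n_machines,
                                 cost = cost, gamma = gamma, conf = conf,
                                 seed = child_seed(seed, 2L * i + 1L))
    )
  }
  out
}
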