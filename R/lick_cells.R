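#' Score cells by lick-predictive information
#'
#' Identifies motor/decision-coupled cells via a selection-and-scoring
#' procedure. Trials are split into a lick group (Hit and FA) and a
#' no-lick group (CR and Miss): inside the response window the stimulus
#' and reward contingencies differ *within* each group, so the only
#' systematic difference between groups is licking itself. For each
#' raster bin inside the response window and each machine, forward
#' sequential feature selection picks the `n_select` most predictive
#' cells; every time a cell is selected it accrues the z-scored held-out
#' accuracy of that machine, so sub-chance machines (< 50% accuracy)
#' contribute negative score, super-chance machines positive score, and
#' exact-chance machines zero. The z-score reference is the accuracy
#' spread of shuffled-label control machines in the same bin.
#'
#' @param raster A `spike_raster`.
#' @param outcomes Labeled `trial_table` for the raster's trials.
#' @param response_window `c(start, end)` seconds (the variant's response
#'   window).
#' @param n_select Cells selected per machine (default 20; clamped to the
#'   population size with a warning).
#' @param n_machines Machines per bin (default 100).
#' @param cost RBF box constraint.
#' @param seed Integer seed.
#' @return A `cell_score_table`: data frame with columns `cell`,
#'   `selection_count`, `total_score`.
#' @export
score_cells <- function(raster, outcomes, response_window = c(1, 2),
                        n_select = 20L, n_machines = 100L, cost = 1,
                        seed = NULL) {
  if (!inherits(raster, "spike_raster"))
    stop_validation("raster must be a spike_raster")
  grp <- ifelse(outcomes$outcome %in% c("Hit", "FA"), "lick",
                ifelse(outcomes$outcome %in% c("CR", "Miss"), "nolick", NA))
  if (anyNA(grp)) stop_validation("outcomes must be labeled first")
  if (length(unique(grp)) < 2L)
    stop_validation("both lick and no-lick trial groups must be non-empty")
  nc <- n_cells(raster)
  if (n_select > nc) {
    warning("n_select exceeds the population size; clamped to ", nc)
    n_select <- nc
  }
  feats <- bin_features(raster, trial_ids = outcomes$trial_id)
  mids <- feats$times + feats$bin_width / 2
  in_win <- which(mids >= response_window[1] & mids < response_window[2])
  if (!length(in_win)) stop_validation("response window contains no raster bins")
  labels <- factor(grp)
  with_seed(seed, {
    counts <- integer(nc)
    scores <- numeric(nc)
    for (b in in_win) {
      x <- feats$bins[[b]]
      if (is.na(median_heuristic_gamma(x))) next
      # the z-score reference needs a stable spread estimate even when few
      # scoring machines are run
      ctrl <- bin_accuracies(x, labels, max(n_machines, 20L), split = 0.8,
                             cost = cost, gamma = NULL, shuffle = TRUE)$accs
      s_ctrl <- sd(ctrl)
      if (!is.finite(s_ctrl) || s_ctrl == 0) s_ctrl <- 1 / sqrt(length(labels))
      for (m in seq_len(n_machines)) {
        train <- stratified_train(labels, 0.8)
        sel <- forward_select(x, labels, train, n_select, cost)
        acc <- fit_predict_acc(x[, sel, drop = FALSE], labels, train,
                               cost, gamma = NULL)
        z <- (acc - 0.5) / s_ctrl
        counts[sel] <- counts[sel] + 1L
        scores[sel] <- scores[sel] + z
      }
    }
    structure(data.frame(cell = seq_len(nc), selection_count = counts,
                         total_score = scores),
              class = c("cell_score_table", "data.frame"))
  })
}

#' Session admission for lick-cell flagging
#'
#' A session's cell scores are trusted only when score and selection count
#' agree: the Pearson correlation between `total_score` and
#' `selection_count` must be positive and significant at level `alpha`.
#' Sessions failing this (unreliable predictability) are not admitted and
#' yield no flagged cells.
#'
#' @param table A `cell_score_table` from [score_cells()].
#' @param alpha Significance level (default 0.05).
#' @return Logical (admitted or not) with attributes `r` and `p`.
#' @export
admit_session <- function(table, alpha = 0.05) {
  if (nrow(table) < 3L) stop_validation("need at least 3 cells")
  if (sd(table$total_score) == 0 || sd(table$selection_count) == 0) {
    warning("constant scores or counts; session not admitted")
    return(structure(FALSE, r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(table$total_score, table$selection_count,
                 alternative = "two.sided", method = "pearson")
  structure(unname(ct$estimate > 0 && ct$p.value < alpha),
            r = unname(ct$estimate), p = ct$p.value)
}

#' Flag lick-modulated cells
#'
#' Within an admitted session, cells whose total score exceeds the mean
#' total score by more than one (sample) standard deviation are flagged as
#' lick modulated. An empty set is a legitimate outcome (some animals
#' have none). Non-admitted sessions yield an empty set with a message.
#'
#' @param table A `cell_score_table`.
#' @param admission Result of [admit_session()]; computed from `table`
#'   when omitted.
#' @return Integer vector of flagged cell ids (possibly empty).
#' @export
flag_lick_cells <- function(table, admission = NULL) {
  if (is.null(admission)) admission <- admit_session(table)
  if (!isTRUE(as.logical(admission))) {
    message("session not admitted; no cells flagged")
    return(integer(0))
  }
  thr <- mean(table$total_score) + sd(table$total_score)
  table$cell[table$total_score > thr]
}

#' Remove cells from a raster
#'
#' Drops the given cells (typically flagged lick-modulated cells) from a
#' raster before sensory analyses. The removed ids are kept in the
#' `removed_cells` attribute for audit.
#'
#' @param raster A `spike_raster`.
#' @param ids Cell ids to remove; must be a subset of the raster's cells.
#' @return The reduced `spike_raster`.
#' @export
remove_cells <- function(raster, ids) {
  if (!inherits(raster, "spike_raster"))
    stop_validation("raster must be a spike_raster")
  nc <- n_cells(raster)
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || any(ids < 1L | ids > nc)))
    stop_validation("unknown cell ids")
  keep <- setdiff(seq_len(nc), ids)
  if (!length(keep)) stop_validation("removing all cells leaves an empty raster")
  out <- raster
  out$activity <- raster$activity[keep, , , drop = FALSE]
  out$cell_flags <- raster$cell_flags[keep]
  out$stim_cells <- raster$stim_cells[keep]
  attr(out, "removed_cells") <- sort(unique(c(attr(raster, "removed_cells"), ids)))
  out
}
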