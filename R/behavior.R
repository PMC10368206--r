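#' Individualized lick-rate threshold
#'
#' The response threshold for each animal is set from its final pretrial
#' session: mean of the per-trial lick rates minus one (sample) standard
#' deviation, floored at zero.
#'
#' @param pretrial_rates Numeric vector of per-trial lick rates (licks/s)
#'   from the last pretrial session; at least two observations.
#' @return Threshold in licks/s.
#' @export
lick_threshold <- function(pretrial_rates) {
  if (!is.numeric(pretrial_rates) || length(pretrial_rates) < 2L)
    stop_validation("need at least two pretrial rate observations")
  max(0, mean(pretrial_rates) - sd(pretrial_rates))
}

# per-trial lick rate (licks/s) inside a window, for every trial of a schedule
window_lick_rates <- function(schedule, licks, window) {
  len <- diff(window)
  counts <- vapply(schedule$trial_id, function(id) {
    t <- licks$time[licks$trial_id == id]
    sum(t >= window[1] & t < window[2])
  }, numeric(1))
  counts / len
}

#' Label trial outcomes from licking
#'
#' Applies the go/no-go contingency: a preferred trial whose mean lick rate
#' over the response window reaches the threshold is a Hit, otherwise a
#' Miss; a nonpreferred trial is a False Alarm (FA) when the rate reaches
#' threshold and a Correct Rejection (CR) otherwise.
#'
#' @param schedule A `trial_table` with `stimulus` labels.
#' @param licks `lick_trains` for the same trials.
#' @param threshold Lick-rate threshold, licks/s (see [lick_threshold()]).
#' @param response_window Numeric `c(start, end)` in seconds; defaults to
#'   the 1–2 s TPSD response window.
#' @return The schedule with `outcome` filled in
#'   (`"Hit"`/`"Miss"`/`"CR"`/`"FA"`).
#' @export
label_outcomes <- function(schedule, licks, threshold,
                           response_window = c(1, 2)) {
  if (!all(schedule$stimulus %in% c("P", "NP")))
    stop_validation("schedule must label every trial P or NP")
  assert_scalar_number(threshold, "threshold")
  rates <- window_lick_rates(schedule, licks, response_window)
  responded <- rates >= threshold
  schedule$outcome <- ifelse(schedule$stimulus == "P",
                             ifelse(responded, "Hit", "Miss"),
                             ifelse(responded, "FA", "CR"))
  schedule
}

#' Discriminability index (d')
#'
#' `d' = qnorm(hit fraction) - qnorm(false-alarm fraction)`, with rates of
#' exactly 1 replaced by 0.99 and rates of exactly 0 replaced by 0.01 so
#' the inverse-normal transform stays finite. No other correction is
#' applied. The clipping bounds |d'| by `2 * qnorm(0.99)` (about 4.653).
#'
#' @param hit_frac Fraction of preferred trials answered with a lick.
#' @param fa_frac Fraction of nonpreferred trials answered with a lick.
#' @return The discriminability index, unitless.
#' @examples
#' dprime(0.84, 0.16)   # ~1.989
#' dprime(1, 0)         # clipped: ~4.653
#' @export
dprime <- function(hit_frac, fa_frac) {
  for (v in c(hit_frac, fa_frac))
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop_validation("rates must lie in [0, 1]")
  clip <- function(p) ifelse(p == 1, 0.99, ifelse(p == 0, 0.01, p))
  qnorm(clip(hit_frac)) - qnorm(clip(fa_frac))
}

#' Best sliding-window d' of a session
#'
#' Slides a contiguous window (default 150 trials) across the labeled
#' session, computes d' from the hit and false-alarm fractions inside each
#' window, and returns the maximum. Hit and CR rates are reported for the
#' same best window. Ties go to the earliest window.
#'
#' @param outcomes A labeled `trial_table` (see [label_outcomes()]).
#' @param window Window length in trials; the session must be at least
#'   this long.
#' @return List with `dprime`, `window_start` (1-based index of the first
#'   trial of the best window), `hit_rate`, `cr_rate`.
#' @export
best_window_dprime <- function(outcomes, window = 150L) {
  n <- nrow(outcomes)
  window <- as.integer(window)
  if (n < window)
    stop_validation("session has ", n, " trials; need at least ", window)
  if (any(outcomes$outcome == "unlabeled"))
    stop_validation("outcomes must be labeled first (label_outcomes)")
  hit  <- cumsum(c(0, outcomes$outcome == "Hit"))
  miss <- cumsum(c(0, outcomes$outcome == "Miss"))
  fa   <- cumsum(c(0, outcomes$outcome == "FA"))
  cr   <- cumsum(c(0, outcomes$outcome == "CR"))
  starts <- seq_len(n - window + 1L)
  ends <- starts + window
  n_hit <- hit[ends] - hit[starts]
  n_miss <- miss[ends] - miss[starts]
  n_fa <- fa[ends] - fa[starts]
  n_cr <- cr[ends] - cr[starts]
  hr <- n_hit / (n_hit + n_miss)
  far <- n_fa / (n_fa + n_cr)
  # windows lacking one stimulus type are undefined; exclude them
  ok <- (n_hit + n_miss) > 0 & (n_fa + n_cr) > 0
  if (!any(ok)) stop_validation("no window contains both stimulus types")
  d <- rep(-Inf, length(starts))
  d[ok] <- dprime(hr[ok], far[ok])
  best <- which.max(d)  # earliest on ties
  list(dprime = d[best],
       window_start = starts[best],
       hit_rate = hr[best],
       cr_rate = 1 - far[best])
}

#' Lick-probability time profiles
#'
#' Per-bin probability of at least one lick in consecutive 0.1 s windows,
#' computed per animal within each group (stage x stimulus x outcome, or
#' any subset of those columns), then averaged across animals. Empty
#' groups are dropped with a message — in practice Miss trials, which are
#' exceedingly rare in trained animals.
#'
#' @param licks `lick_trains`; may carry a `mouse` column for multi-animal
#'   data (a single pseudo-animal is assumed otherwise).
#' @param outcomes Labeled `trial_table`, matched by `trial_id` (and
#'   `mouse` when present).
#' @param group_by Character vector of grouping columns from `outcomes`
#'   (default `c("stage", "stimulus", "outcome")`).
#' @param bin_width Bin width in seconds (default 0.1).
#' @param horizon Profile duration in seconds; defaults to the lick-train
#'   horizon.
#' @return A long data frame with columns `group` columns, `time` (bin
#'   start), `probability`, of class `lick_probability_curve`.
#' @export
lick_probability_profile <- function(licks, outcomes,
                                     group_by = c("stage", "stimulus", "outcome"),
                                     bin_width = 0.1, horizon = NULL) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(horizon)) horizon <- attr(licks, "horizon")
  if (is.null(horizon)) horizon <- max(licks$time, 1) + bin_width
  if (!all(group_by %in% names(outcomes)))
    stop_validation("group_by columns missing from outcomes")
  n_bins <- floor(horizon / bin_width)
  has_mouse <- "mouse" %in% names(outcomes)
  if (!has_mouse) {
    outcomes$mouse <- rep("m1", nrow(outcomes))
    licks$mouse <- rep("m1", nrow(licks))
  }
  key_out <- do.call(paste, c(outcomes[group_by], sep = "|"))
  groups <- unique(key_out)
  res <- list()
  for (g in groups) {
    rows <- outcomes[key_out == g, , drop = FALSE]
    if (!nrow(rows)) next
    per_mouse <- lapply(split(rows, rows$mouse), function(rr) {
      lk <- licks[licks$mouse %in% rr$mouse[1] &
                    licks$trial_id %in% rr$trial_id, , drop = FALSE]
      hit <- matrix(FALSE, nrow(rr), n_bins)
      if (nrow(lk)) {
        i <- match(lk$trial_id, rr$trial_id)
        j <- floor(lk$time / bin_width) + 1L
        keep <- j <= n_bins
        hit[cbind(i[keep], j[keep])] <- TRUE
      }
      colMeans(hit)
    })
    prob <- Reduce(`+`, per_mouse) / length(per_mouse)
    gvals <- strsplit(g, "|", fixed = TRUE)[[1]]
    d <- as.data.frame(setNames(as.list(gvals), group_by),
                       stringsAsFactors = FALSE)
    res[[g]] <- cbind(d[rep(1, n_bins), , drop = FALSE],
                      time = (seq_len(n_bins) - 1) * bin_width,
                      probability = prob)
  }
  empty <- setdiff(groups, names(res))
  if (length(empty)) message("dropped empty groups: ",
                             paste(empty, collapse = ", "))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("lick_probability_curve", "data.frame")
  out
}
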