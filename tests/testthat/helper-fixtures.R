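# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

tpsd_variant <- task_variant("TPSD")

# a small labeled session in a given stage
small_session <- function(stage = "learned", n_trials = 120, ratio = 0.5,
                          n_cells = 20, seed = 1, ...) {
  fx <- make_fixture(list(stage = stage, n_trials = n_trials, ratio = ratio,
                          pretrial_trials = 40,
                          population = c(list(n_cells = n_cells), list(...))),
                     seed = seed)
  pre <- tpsd:::window_lick_rates(fx$pretrial_schedule, fx$pretrial_licks,
                                  tpsd_variant$response_window)
  thr <- lick_threshold(pre)
  fx$outcomes <- label_outcomes(fx$schedule, fx$licks, thr,
                                tpsd_variant$response_window)
  fx$threshold <- thr
  fx
}

# hand-built binned_features with one strongly informative column
informative_features <- function(n = 80, n_feat = 8, informative = 4,
                                 seed = 1) {
  set.seed(seed)
  lab <- rep(c("P", "NP"), each = n / 2)
  x <- matrix(rbinom(n * n_feat, 1, 0.1), n, n_feat)
  x[, informative] <- rbinom(n, 1, ifelse(lab == "P", 0.85, 0.08))
  list(features = structure(list(bins = list(x), times = 0,
                                 bin_width = 1 / 15, trial_ids = seq_len(n),
                                 type = "spikes"),
                            class = "binned_features"),
       labels = lab)
}

# brute-force two-sample KS statistic: max ECDF gap over pooled points
ks_stat_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# brute-force best-window d-prime (independent of the cumsum path)
best_window_brute <- function(outcomes, window) {
  n <- nrow(outcomes)
  best <- -Inf
  best_start <- NA
  for (s in seq_len(n - window + 1)) {
    w <- outcomes$outcome[s:(s + window - 1)]
    nh <- sum(w == "Hit"); nm <- sum(w == "Miss")
    nf <- sum(w == "FA"); ncr <- sum(w == "CR")
    if (nh + nm == 0 || nf + ncr == 0) next
    d <- dprime(nh / (nh + nm), nf / (nf + ncr))
    if (d > best) {
      best <- d
      best_start <- s
    }
  }
  list(dprime = best, window_start = best_start)
}

# inverse normal through an independent route (error function), for the
# d-prime oracle
qnorm_erfinv <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)
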