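test_that("bootstrap mean activity handles degenerate and single-trial
           input", {
  sch <- build_session_schedule(task_variant("TPSD"), 8, 0.5, seed = 1)
  spec <- population_spec(n_cells = 4, fraction_stim_locked = 0,
                          fraction_lick_cells = 0, base_p = 1,
                          stage = "naive")
  r <- simulate_population(sch, task_variant("TPSD"), spec, horizon = 1,
                           seed = 2)
  # base_p = 1: every entry fires; mean 1 with a zero-width interval
  s <- bootstrap_mean_activity(r, n_iter = 50, seed = 3)
  expect_true(all(s$mean == 1))
  expect_true(all(s$lo == 1 & s$hi == 1))

  s1 <- bootstrap_mean_activity(r, trials = 3, n_iter = 20, seed = 4)
  expect_equal(nrow(unique(attr(s1, "iterations"))), 1)  # one trial only

  expect_error(bootstrap_mean_activity(r, trials = 99), "trials")
})

test_that("bootstrap summaries pool across animals into a grand
           distribution", {
  fx1 <- small_session(stage = "naive", n_trials = 30, n_cells = 6, seed = 5)
  fx2 <- small_session(stage = "naive", n_trials = 30, n_cells = 6, seed = 6)
  s1 <- bootstrap_mean_activity(fx1$raster, n_iter = 40, seed = 7)
  s2 <- bootstrap_mean_activity(fx2$raster, n_iter = 40, seed = 8)
  pooled <- pool_network_summaries(list(s1, s2))
  expect_equal(nrow(attr(pooled, "iterations")), 80)
  expect_equal(pooled$mean, (s1$mean + s2$mean) / 2, tolerance = 1e-12)
})

test_that("stimulus correlation recovers sign and nulls on independence", {
  iters <- matrix(rep(c(0, 1, 0, 1), each = 50), nrow = 50)
  s <- structure(data.frame(time = 1:4, mean = c(0, 1, 0, 1),
                            lo = 0, hi = 1),
                 iterations = iters, class = c("network_summary", "data.frame"))
  expect_equal(stimulus_correlation(s, c(0, 1, 0, 1))$r, 1)
  expect_equal(stimulus_correlation(s, c(1, 0, 1, 0))$r, -1)
  expect_error(stimulus_correlation(s, c(1, 1, 1, 1)), "zero-variance")
  expect_error(stimulus_correlation(s, c(0, 1)), "bin grids")

  set.seed(9)
  noise <- matrix(rnorm(100 * 100), 100)
  sn <- structure(data.frame(time = 1:100, mean = colMeans(noise),
                             lo = 0, hi = 1),
                  iterations = noise,
                  class = c("network_summary", "data.frame"))
  expect_lt(abs(stimulus_correlation(sn, rep(c(0, 1), 50))$r), 0.05)
})

test_that("bootstrap confidence intervals cover the generating mean", {
  # known per-bin firing probability; check 95% CI coverage across
  # replicates of small populations
  covered <- 0
  n_rep <- 60
  sch <- build_session_schedule(task_variant("TPSD"), 25, 0.5, seed = 1)
  spec <- population_spec(n_cells = 8, fraction_stim_locked = 0,
                          fraction_lick_cells = 0, base_p = 0.15,
                          stage = "naive")
  for (i in seq_len(n_rep)) {
    r <- simulate_population(sch, task_variant("TPSD"), spec, horizon = 0.3,
                             seed = 100 + i)
    s <- bootstrap_mean_activity(r, n_iter = 200, seed = 200 + i)
    covered <- covered + (s$lo[1] <= 0.15 && 0.15 <= s$hi[1])
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("peak times take the earliest maximal bin and KS comparisons
           apply the Bonferroni family correction", {
  sch <- build_session_schedule(task_variant("TPSD"), 4, 0.5, seed = 10)
  act <- array(0L, dim = c(3, 10, 4))
  act[1, 4, ] <- 1L              # fires only in bin 4
  act[2, c(2, 7), 1:2] <- 1L     # tie between bins 2 and 7 -> earliest
  raster <- structure(list(activity = act, bin_width = 1 / 15,
                           times = (0:9) / 15, cell_flags = rep(FALSE, 3),
                           stim_cells = rep(FALSE, 3), stage = "naive",
                           trial_ids = 1:4),
                      class = "spike_raster")
  pt <- peak_times(raster, period = c(0, 10 / 15))
  expect_equal(pt$peak_time[1], 3 / 15)
  expect_equal(pt$peak_time[2], 1 / 15)
  expect_equal(pt$peak_time[3], 0)       # flat cell -> first bin of period
  expect_error(peak_times(raster, period = c(0.5, 0.2)), "period")

  # Bonferroni-adjusted alphas at 4-decimal rounding
  dists <- list(a = rnorm(40), b = rnorm(40), c = rnorm(40), d = rnorm(40))
  res6 <- compare_peak_distributions(dists)
  expect_equal(nrow(res6), 6)
  expect_equal(round(res6$alpha_adj[1], 4), 0.0083)
  res3 <- compare_peak_distributions(dists[1:3])
  expect_equal(round(res3$alpha_adj[1], 4), 0.0167)

  same <- compare_peak_distributions(list(x = 1:30, y = 1:30))
  expect_equal(same$D, 0)
  expect_false(same$significant)
})

test_that("two-sample KS statistic equals the brute-force ECDF gap", {
  set.seed(11)
  for (i in 1:8) {
    a <- sample(0:20, sample(5:50, 1), replace = TRUE) / 15
    b <- sample(0:20, sample(5:50, 1), replace = TRUE) / 15
    got <- compare_peak_distributions(list(a = a, b = b))$D
    expect_equal(got, ks_stat_brute(a, b), tolerance = 1e-12)
  }
})

test_that("peak-time sorting equals the argsort oracle", {
  d <- diag(5)
  expect_equal(sort_by_peak_time(d), 1:5)
  expect_equal(sort_by_peak_time(d[, 5:1]), 5:1)
  set.seed(12)
  tr <- matrix(runif(40 * 12), 40)
  peak <- apply(tr, 1, which.max)
  expect_equal(sort_by_peak_time(tr), order(peak, seq_len(40)))
})

test_that("trajectories expose low-rank structure and outcome divergence", {
  # activity confined to a 2-D subspace: two components explain ~100%
  set.seed(13)
  base <- matrix(rnorm(2 * 12), 2, 12)
  mix <- matrix(rnorm(6 * 2), 6, 2)
  act <- array(0L, dim = c(6, 12, 4))
  template <- (mix %*% base > 0) * 1L
  for (tr in 1:4) act[, , tr] <- template
  raster <- structure(list(activity = act, bin_width = 1 / 15,
                           times = (0:11) / 15, cell_flags = rep(FALSE, 6),
                           stim_cells = rep(FALSE, 6), stage = "naive",
                           trial_ids = 1:4),
                      class = "spike_raster")
  oc <- data.frame(trial_id = 1:4, stimulus = "P", stage = "naive",
                   outcome = c("Hit", "Hit", "CR", "CR"))
  tj <- outcome_trajectories(raster, oc)
  # identical activity across outcomes: zero divergence
  expect_equal(trajectory_divergence(tj, "Hit", "CR"), 0)
  expect_equal(names(tj$trajectories), c("Hit", "CR"))

  fx <- small_session(stage = "learned", n_trials = 120, n_cells = 20,
                      seed = 14)
  tj2 <- outcome_trajectories(fx$raster, fx$outcomes)
  expect_true(all(tj2$variance_explained >= 0))
  expect_lte(sum(tj2$variance_explained), 100 + 1e-9)
  # variance explained is invariant to cell permutation
  perm <- sample(n_cells(fx$raster))
  r_perm <- fx$raster
  r_perm$activity <- fx$raster$activity[perm, , ]
  r_perm$cell_flags <- fx$raster$cell_flags[perm]
  r_perm$stim_cells <- fx$raster$stim_cells[perm]
  tj3 <- outcome_trajectories(r_perm, fx$outcomes)
  expect_equal(tj3$variance_explained, tj2$variance_explained,
               tolerance = 1e-9)
})
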