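test_that("feature binning follows the floor convention and maps rasters 1:1", {
  lk <- data.frame(trial_id = integer(0), time = numeric(0))
  attr(lk, "horizon") <- 2
  class(lk) <- c("lick_trains", "data.frame")
  f <- bin_features(lk, trial_ids = 1:4, bin_width = 0.067, horizon = 2)
  expect_equal(length(f$bins), 29)  # floor(2 / 0.067)
  expect_true(all(vapply(f$bins, function(b) all(b == 0), logical(1))))
  expect_equal(dim(f$bins[[1]]), c(4, 1))

  sch <- build_session_schedule(task_variant("TPSD"), 6, 0.5, seed = 1)
  spec <- population_spec(n_cells = 4, fraction_stim_locked = 0,
                          fraction_lick_cells = 0, stage = "naive")
  r <- simulate_population(sch, task_variant("TPSD"), spec, horizon = 1,
                           seed = 2)
  fr <- bin_features(r)
  expect_equal(length(fr$bins), length(r$times))
  for (k in c(1, 7, 15))
    expect_identical(fr$bins[[k]], t(r$activity[, k, ]))
})

test_that("decoder recovers separable structure and nulls out shuffles", {
  inf <- informative_features(n = 80, seed = 3)
  cv <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 60,
                            seed = 4)
  expect_gte(cv$mean_acc, 0.8)
  expect_true(all(attr(cv, "accs") >= 0 & attr(cv, "accs") <= 1))

  ct <- shuffled_control(inf$features, inf$labels, n_machines = 100,
                         seed = 5)
  se <- sd(attr(ct, "accs")) / sqrt(100)
  expect_lt(abs(ct$mean_acc - 0.5), 3 * se + 1e-9)
  expect_true(ct$lo <= 0.5 & ct$hi >= 0.5)

  # single machine, fixed seed: reproducible
  a1 <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 1, seed = 6)
  a2 <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 1, seed = 6)
  expect_identical(a1$mean_acc, a2$mean_acc)

  expect_error(bootstrap_svm_curve(inf$features, rep("P", 80)), "classes")
})

test_that("constant-feature bins are recorded at chance with a warning", {
  x <- matrix(0L, 40, 3)
  f <- structure(list(bins = list(x), times = 0, bin_width = 1 / 15,
                      trial_ids = 1:40, type = "spikes"),
                 class = "binned_features")
  lab <- rep(c("P", "NP"), 20)
  expect_warning(cv <- bootstrap_svm_curve(f, lab, n_machines = 10, seed = 1),
                 "degenerate")
  expect_equal(cv$mean_acc, 0.5)
})

test_that("accuracy is invariant to positive feature scaling under the
           median-heuristic kernel scale", {
  inf <- informative_features(n = 60, seed = 8)
  scaled <- inf$features
  scaled$bins <- lapply(scaled$bins, function(b) b * 37.5)
  a1 <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 20, seed = 9)
  a2 <- bootstrap_svm_curve(scaled, inf$labels, n_machines = 20, seed = 9)
  expect_equal(a1$mean_acc, a2$mean_acc)
})

test_that("smaller machine counts widen the band but keep the mean", {
  inf <- informative_features(n = 80, seed = 10)
  small <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 40,
                               seed = 11)
  big <- bootstrap_svm_curve(inf$features, inf$labels, n_machines = 200,
                             seed = 12)
  se <- sd(attr(big, "accs")) / sqrt(40)
  expect_lt(abs(small$mean_acc - big$mean_acc), 4 * se)
})

test_that("hyperparameter tuning searches a log space and degrades safely", {
  inf <- informative_features(n = 60, seed = 13)
  x <- inf$features$bins[[1]]
  t1 <- tune_hyperparameters(x, inf$labels, budget = 1, seed = 14)
  expect_equal(t1$cost, 1)  # first candidate is the default pair
  t8 <- tune_hyperparameters(x, inf$labels, budget = 8, seed = 14)
  expect_gte(t8$cv_accuracy, t1$cv_accuracy)
  expect_gte(t8$cv_accuracy, 0.7)

  # pure noise: CV accuracy stays near chance
  set.seed(15)
  xn <- matrix(rnorm(60 * 4), 60, 4)
  tn <- tune_hyperparameters(xn, inf$labels, budget = 4, seed = 16)
  expect_lt(abs(tn$cv_accuracy - 0.5), 3 * sqrt(0.25 / 60) + 0.05)

  few <- c(1:3, 31:33)  # three trials per class: too few for 5 folds
  expect_warning(tune_hyperparameters(x[few, ], inf$labels[few], folds = 5),
                 "default")
})

test_that("k-cell forward selection finds informative cells and saturates
           when forced", {
  inf <- informative_features(n = 80, n_feat = 8, informative = 4, seed = 17)
  r <- kcell_selection_curve(inf$features, inf$labels, k = 1,
                             n_machines = 40, seed = 18)
  expect_gt(r$selection_map[1, 4], 0.5)
  expect_gte(r$curve$mean_acc, 0.7)
  expect_true(all(abs(rowSums(r$selection_map) - 1) < 1e-9))

  # k = n_cells: every cell selected in every machine, uniform map
  rf <- kcell_selection_curve(inf$features, inf$labels, k = 8,
                              n_machines = 5, seed = 19)
  expect_equal(unname(rf$selection_map[1, ]), rep(1 / 8, 8))

  # shuffled labels: chance accuracy
  set.seed(20)
  rs <- kcell_selection_curve(inf$features, sample(inf$labels), k = 2,
                              n_machines = 30, seed = 21)
  expect_lt(abs(rs$curve$mean_acc - 0.5), 0.12)

  expect_error(kcell_selection_curve(inf$features, inf$labels, k = 9), "k")
})

test_that("pairwise outcome decoding mirrors the learned-regime structure", {
  fx <- small_session(stage = "learned", n_trials = 140, n_cells = 25,
                      seed = 23)
  res <- pairwise_outcome_decoding(fx$raster, fx$outcomes, n_machines = 15,
                                   horizon = 1.5, seed = 24)
  expect_true("Hit_vs_CR" %in% names(res))
  hc <- res$Hit_vs_CR
  # suppression after 0.7 s separates Hit and CR before the reward bin
  pre_reward <- hc$curve$time + 1 / 15 >= 0.7 & hc$curve$time < 1.2
  expect_true(any(hc$curve$mean_acc[pre_reward] >
                    hc$control$hi[pre_reward]))

  # an empty class is skipped with a message
  oc <- fx$outcomes
  oc$outcome[oc$outcome == "FA"] <- "CR"
  expect_message(
    res2 <- pairwise_outcome_decoding(fx$raster, oc, n_machines = 2,
                                      horizon = 0.3, seed = 25),
    "skipping")
  expect_false("Hit_vs_FA" %in% names(res2))
})
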