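test_that("lick simulation is reproducible and respects rate structure", {
  v <- task_variant("TPSD")
  sch <- build_session_schedule(v, 250, 0.5, seed = 1, stage = "learned")
  prof <- behavior_profile("learned")
  lk <- simulate_licking(sch, v, prof, seed = 5)
  lk2 <- simulate_licking(sch, v, prof, seed = 5)
  expect_identical(lk, lk2)
  # timestamps on the 250 Hz grid, sorted within trial, inside horizon
  expect_true(all(abs(lk$time * 250 - round(lk$time * 250)) < 1e-9))
  expect_true(all(lk$time >= 0 & lk$time < attr(lk, "horizon")))
  expect_true(all(tapply(lk$time, lk$trial_id, function(t) !is.unsorted(t))))

  # zero rates give empty trains
  silent <- behavior_profile("naive", base_rate = 0, baseline_rate = 0,
                             reward_gain = 0)
  expect_equal(nrow(simulate_licking(sch, v, silent, seed = 1)), 0)

  # learned nonpreferred licking collapses after the suppression onset
  np <- sch$trial_id[sch$stimulus == "NP"]
  lk_np <- lk[lk$trial_id %in% np, ]
  early <- sum(lk_np$time >= 0 & lk_np$time < 0.7) / (0.7 * length(np))
  late <- sum(lk_np$time >= 0.8 & lk_np$time < 2.0) / (1.2 * length(np))
  expect_lt(late, early)
})

test_that("behavior profile validates its parameters", {
  expect_error(behavior_profile("naive", base_rate = -1), "non-negative")
  expect_error(behavior_profile("learned", stim_gain_P = 1, stim_gain_NP = 2),
               "stim_gain_NP")
})

test_that("population generator produces the planted regimes", {
  v <- task_variant("TPSD")
  sch <- build_session_schedule(v, 200, 0.5, seed = 2, stage = "naive")

  # no stimulus-locked and no lick cells in the naive stage: per-bin mean
  # activity is flat (no bin beyond 4 SE of the grand mean)
  spec0 <- population_spec(n_cells = 30, fraction_stim_locked = 0,
                           fraction_lick_cells = 0, stage = "naive")
  r0 <- simulate_population(sch, v, spec0, seed = 3)
  per_bin <- apply(r0$activity, 2, mean)
  grand <- mean(per_bin)
  se <- sd(per_bin) / sqrt(length(per_bin))
  expect_true(all(abs(per_bin - grand) < 4 * sd(per_bin)))
  expect_true(all(r0$activity %in% c(0L, 1L)))

  # planted lick cell at full coupling: spikes track binned licks
  prof <- behavior_profile("naive")
  lk <- simulate_licking(sch, v, prof, seed = 4)
  spec1 <- population_spec(n_cells = 10, fraction_lick_cells = 0.2,
                           lick_coupling = 1, lick_reliability = 1,
                           stage = "naive")
  r1 <- simulate_population(sch, v, spec1, licks = lk, seed = 5)
  counts <- tpsd:::bin_lick_counts(lk, sch$trial_id, r1$bin_width,
                                   length(r1$times))
  for (cell in which(r1$cell_flags)) {
    spikes <- t(r1$activity[cell, , ])
    expect_gt(cor(as.numeric(counts), as.numeric(spikes)), 0.5)
  }

  # zero rate floor gives an all-zero raster
  spec_zero <- population_spec(n_cells = 5, base_p = 0,
                               fraction_stim_locked = 0,
                               fraction_lick_cells = 0, stage = "naive")
  rz <- simulate_population(sch, v, spec_zero, seed = 6)
  expect_equal(sum(rz$activity), 0)

  # lick cells require lick trains
  expect_error(simulate_population(sch, v,
                                   population_spec(n_cells = 5, stage = "naive")),
               "licks")

  # stimulus-locked cells are elevated during preferred on-epochs
  sch_p <- build_session_schedule(v, 150, 0.9, seed = 7, stage = "learned")
  lk_p <- simulate_licking(sch_p, v, behavior_profile("learned"), seed = 7)
  spec2 <- population_spec(n_cells = 30, fraction_stim_locked = 0.5,
                           fraction_lick_cells = 0, stage = "learned")
  r2 <- simulate_population(sch_p, v, spec2, licks = lk_p, seed = 8)
  ind <- stimulus_indicator(build_timeline(v, "P"), r2$bin_width, 4.5)
  ind <- ind[seq_along(r2$times)]
  p_idx <- which(sch_p$stimulus == "P")
  stim_act <- apply(r2$activity[r2$stim_cells, , p_idx, drop = FALSE], 2, mean)
  expect_gt(mean(stim_act[ind == 1]), mean(stim_act[ind == 0 & r2$times < 1.4]))
})

test_that("fixture bundles are self-consistent and round-trip losslessly", {
  fx <- make_fixture(list(n_trials = 10, pretrial_trials = 5,
                          population = list(n_cells = 5)), seed = 9)
  expect_true(all(fx$schedule$outcome == "unlabeled"))
  expect_equal(dim(fx$raster$activity)[3], 10)

  dir <- tempfile("fixture")
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_equal(back$schedule$stimulus, fx$schedule$stimulus)
  expect_identical(back$raster$activity, fx$raster$activity)
  expect_equal(back$licks$time, fx$licks$time)
  expect_equal(back$licks$trial_id, fx$licks$trial_id)
  expect_identical(back$raster$cell_flags, fx$raster$cell_flags)
  expect_equal(back$ground_truth, fx$ground_truth)
  unlink(dir, recursive = TRUE)

  # different seeds: different rasters, identical schema
  fx2 <- make_fixture(list(n_trials = 10, pretrial_trials = 5,
                           population = list(n_cells = 5)), seed = 10)
  expect_false(identical(fx$raster$activity, fx2$raster$activity))
  expect_identical(dim(fx$raster$activity), dim(fx2$raster$activity))

  expect_error(make_fixture(list(nonsense_key = 1)), "unknown")
})

test_that("default population size is drawn from the field-of-view
           distribution, truncated below", {
  sch <- build_session_schedule(task_variant("TPSD"), 5, 0.5, seed = 1)
  spec <- population_spec(fraction_stim_locked = 0, fraction_lick_cells = 0,
                          stage = "naive")
  draws <- vapply(1:40, function(s)
    n_cells(simulate_population(sch, task_variant("TPSD"), spec,
                                horizon = 0.5, seed = s)), numeric(1))
  expect_true(all(draws >= 10))
  # mean within 4 SE of 108 under SD 39.2
  expect_lt(abs(mean(draws) - 108), 4 * 39.2 / sqrt(length(draws)))
  expect_gt(sd(draws), 10)
})
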