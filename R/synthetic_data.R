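#' Licking-behavior profile for the synthetic generator
#'
#' Parameterizes the inhomogeneous lick-rate function used by
#' [simulate_licking()]. Mouse licking is bouty: on each trial the animal
#' either commits to a lick bout or largely withholds licking, so the
#' generator draws a per-trial *respond* decision and shapes the rate
#' around it.
#'
#' * Respond trials lick at `base_rate` early in the trial, ramp to
#'   `base_rate * stim_gain_P` from `anticipation_onset`, gain a
#'   `reward_gain` consumption boost on rewarded trials between the water
#'   delivery and the vacuum, and fall back to `baseline_rate` after the
#'   response window closes.
#' * Non-respond trials lick sparsely at `baseline_rate` throughout.
#' * In the naive stage the respond decision is stimulus independent
#'   (probability `respond_prob`): before the water arrives, licking
#'   carries no stimulus information.
#' * In the learned stage preferred trials are answered with probability
#'   `respond_prob` while nonpreferred trials are answered (a lapse — the
#'   future false alarms) only with probability `lapse_prob`. Engaged
#'   nonpreferred trials begin at `base_rate * stim_gain_NP` and are
#'   exponentially suppressed from `suppression_onset` (nominally 0.7 s,
#'   where behavior and network activity diverge with learning) with time
#'   constant `suppression_tau`.
#'
#' @param stage `"naive"` or `"learned"`.
#' @param base_rate Early-trial lick rate on engaged trials, licks/s.
#' @param stim_gain_P Multiplicative response-bout gain from
#'   `anticipation_onset` on respond trials.
#' @param stim_gain_NP Gain on engaged nonpreferred trials before
#'   suppression (learned stage).
#' @param baseline_rate Sparse licking rate outside bouts, licks/s.
#' @param reward_gain Consumption gain on rewarded respond trials between
#'   reward delivery and the vacuum.
#' @param respond_prob Probability of committing to a response bout
#'   (stimulus independent when naive; preferred trials when learned).
#' @param lapse_prob Learned-stage probability of failing to suppress on a
#'   nonpreferred trial.
#' @param suppression_onset Start of learned nonpreferred lick
#'   suppression, seconds.
#' @param suppression_tau Exponential decay constant of the suppression,
#'   seconds.
#' @param anticipation_onset Start of the response bout, seconds.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(stage = c("naive", "learned"),
                             base_rate = 4,
                             stim_gain_P = 2,
                             stim_gain_NP = 1,
                             baseline_rate = 0.5,
                             reward_gain = 1.5,
                             respond_prob = if (stage == "learned") 0.97 else 0.55,
                             lapse_prob = if (stage == "learned") 0.12 else 0,
                             suppression_onset = 0.7,
                             suppression_tau = 0.3,
                             anticipation_onset = 0.5) {
  stage <- match.arg(stage)
  for (nm in c("base_rate", "stim_gain_P", "stim_gain_NP", "baseline_rate",
               "reward_gain")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v < 0) stop_validation(nm, " must be non-negative")
  }
  assert_fraction(lapse_prob, "lapse_prob")
  assert_fraction(respond_prob, "respond_prob")
  if (stage == "learned" && stim_gain_NP > stim_gain_P)
    stop_validation("learned profile requires stim_gain_NP <= stim_gain_P")
  structure(list(stage = stage, base_rate = base_rate,
                 stim_gain_P = stim_gain_P, stim_gain_NP = stim_gain_NP,
                 baseline_rate = baseline_rate,
                 reward_gain = reward_gain,
                 respond_prob = respond_prob,
                 lapse_prob = lapse_prob,
                 suppression_onset = suppression_onset,
                 suppression_tau = suppression_tau,
                 anticipation_onset = anticipation_onset),
            class = "behavior_profile")
}

# Instantaneous lick rate (licks/s) at times t for one trial.
# `respond`: the trial-level bout decision (on NP learned trials a lapse).
lick_rate_fun <- function(t, stimulus, profile, variant, respond) {
  resp_end <- variant$response_window[2]
  engaged_np <- profile$stage == "learned" && stimulus == "NP" && !respond
  if (engaged_np) {
    r <- rep(profile$base_rate * profile$stim_gain_NP, length(t))
    sup <- t >= profile$suppression_onset
    r[sup] <- r[sup] *
      exp(-(t[sup] - profile$suppression_onset) / profile$suppression_tau)
    r[t >= resp_end] <- profile$baseline_rate
    return(pmax(r, profile$baseline_rate * (t < resp_end)))
  }
  if (!respond) return(rep(profile$baseline_rate, length(t)))
  r <- rep(profile$base_rate, length(t))
  bout <- t >= profile$anticipation_onset & t < resp_end
  r[bout] <- profile$base_rate * profile$stim_gain_P
  if (stimulus == "P") {
    rew <- t >= variant$reward_time & t < resp_end
    r[rew] <- r[rew] * profile$reward_gain
  }
  r[t >= resp_end] <- profile$baseline_rate
  r
}

#' Simulate lick-event trains for a trial schedule
#'
#' Draws per-trial lick events as an inhomogeneous Bernoulli process on the
#' 250 Hz lickport clock, with the rate function defined by a
#' [behavior_profile()]. Timestamps are trial-relative (t = 0 at first
#' stimulus onset) and lie on the 1/250 s grid.
#'
#' @param schedule A `trial_table` from [build_session_schedule()].
#' @param variant The [task_variant()] of the schedule.
#' @param profile A [behavior_profile()].
#' @param horizon Trial duration simulated, seconds.
#' @param seed Integer seed; identical seeds reproduce identical trains.
#' @return An object of class `lick_trains`: a data frame with columns
#'   `trial_id` and `time`, and attributes `horizon`, `clock_hz` (250) and
#'   `lapse` (per-trial logical, learned nonpreferred lapses).
#' @export
simulate_licking <- function(schedule, variant, profile, horizon = 4.5,
                             seed = NULL) {
  if (!inherits(profile, "behavior_profile"))
    stop_validation("profile must be a behavior_profile object")
  if (!inherits(variant, "task_variant"))
    stop_validation("variant must be a task_variant object")
  if (!all(schedule$stimulus %in% c("P", "NP")))
    stop_validation("schedule must label every trial P or NP")
  assert_scalar_number(horizon, "horizon", positive = TRUE)
  hz <- 250L
  ticks <- (seq_len(floor(horizon * hz)) - 1L) / hz
  with_seed(seed, {
    n <- nrow(schedule)
    np <- schedule$stimulus == "NP"
    respond <- logical(n)
    if (profile$stage == "naive") {
      respond <- runif(n) < profile$respond_prob
    } else {
      respond[!np] <- runif(sum(!np)) < profile$respond_prob
      respond[np] <- runif(sum(np)) < profile$lapse_prob
    }
    lapse <- respond & np & profile$stage == "learned"
    trains <- lapply(seq_len(n), function(i) {
      rate <- lick_rate_fun(ticks, schedule$stimulus[i], profile, variant,
                            respond = respond[i])
      p <- pmin(rate / hz, 1)
      ticks[runif(length(ticks)) < p]
    })
    out <- data.frame(
      trial_id = rep(schedule$trial_id, lengths(trains)),
      time = unlist(trains)
    )
    attr(out, "horizon") <- horizon
    attr(out, "clock_hz") <- hz
    attr(out, "respond") <- respond
    attr(out, "lapse") <- lapse
    class(out) <- c("lick_trains", "data.frame")
    out
  })
}

# licks -> trials x bins count matrix on a fixed grid
bin_lick_counts <- function(licks, trial_ids, bin_width, n_bins) {
  counts <- matrix(0L, nrow = length(trial_ids), ncol = n_bins)
  if (nrow(licks)) {
    keep <- licks$time < n_bins * bin_width & licks$trial_id %in% trial_ids
    lk <- licks[keep, , drop = FALSE]
    if (nrow(lk)) {
      i <- match(lk$trial_id, trial_ids)
      j <- floor(lk$time / bin_width) + 1L
      for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
    }
  }
  counts
}

#' Population specification for the synthetic spike-raster generator
#'
#' Describes a layer-2/3 population imaged at 15 Hz. When `n_cells` is
#' `NULL` the population size is drawn from a normal distribution with
#' mean 108 and SD 39.2 (the across-animal field-of-view statistics the
#' generator emulates), truncated below at 10 cells.
#'
#' @param n_cells Number of cells, or `NULL` to draw.
#' @param frame_rate Imaging rate; fixed at 15 Hz.
#' @param fraction_stim_locked Fraction of cells with stimulus-locked drive.
#' @param fraction_lick_cells Fraction of planted lick-coupled cells.
#' @param base_p Baseline per-bin spike probability.
#' @param stim_coef Logit drive of stimulus-locked cells during preferred
#'   on-epochs in the learned stage.
#' @param naive_stim_coef Logit drive during on-epochs of the presented
#'   pattern in the naive stage (weak, untuned sensory response).
#' @param suppression_onset,suppression_tau Learned nonpreferred network
#'   suppression: from `suppression_onset` seconds the log-odds of every
#'   cell decay linearly with slope `1/suppression_tau` on engaged
#'   (non-lapse) nonpreferred trials.
#' @param lick_coupling Coupling strength in `[0, 1]` of planted lick cells:
#'   their spike probability is a `lick_coupling`-weighted mixture of the
#'   lick-driven component and the background component.
#' @param stage `"naive"` or `"learned"`.
#' @param mean_cells,sd_cells Parameters of the population-size draw.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = NULL, frame_rate = 15,
                            fraction_stim_locked = 0.3,
                            fraction_lick_cells = 0.1,
                            base_p = 0.08,
                            stim_coef = 1.2,
                            naive_stim_coef = 0.4,
                            suppression_onset = 0.7,
                            suppression_tau = 0.45,
                            lick_coupling = 0.8,
                            lick_reliability = 0.8,
                            stage = c("naive", "learned"),
                            mean_cells = 108, sd_cells = 39.2) {
  stage <- match.arg(stage)
  if (!identical(as.numeric(frame_rate), 15))
    stop_validation("frame_rate is fixed at 15 Hz")
  assert_fraction(fraction_stim_locked, "fraction_stim_locked")
  assert_fraction(fraction_lick_cells, "fraction_lick_cells")
  assert_fraction(base_p, "base_p")
  assert_fraction(lick_coupling, "lick_coupling")
  assert_fraction(lick_reliability, "lick_reliability")
  if (!is.null(n_cells)) {
    assert_scalar_number(n_cells, "n_cells", positive = TRUE)
    n_cells <- as.integer(n_cells)
  }
  structure(list(n_cells = n_cells, frame_rate = 15,
                 fraction_stim_locked = fraction_stim_locked,
                 fraction_lick_cells = fraction_lick_cells,
                 base_p = base_p, stim_coef = stim_coef,
                 naive_stim_coef = naive_stim_coef,
                 suppression_onset = suppression_onset,
                 suppression_tau = suppression_tau,
                 lick_coupling = lick_coupling,
                 lick_reliability = lick_reliability,
                 stage = stage,
                 mean_cells = mean_cells, sd_cells = sd_cells),
            class = "population_spec")
}

#' Simulate a deconvolved spike raster
#'
#' Generates a binary cells x bins x trials raster at 15 Hz with the three
#' response regimes the downstream analyses assume:
#'
#' * stimulus-locked cells fire preferentially during stimulus on-epochs —
#'   in the naive stage a weak response to the pattern actually presented,
#'   in the learned stage a strong drive locked to the *preferred* pattern
#'   on all trials (predictive coding of the rewarded rhythm);
#' * on learned nonpreferred trials where the animal withheld licking, the
#'   whole network is progressively suppressed after `suppression_onset`;
#'   on lapse (false-alarm-like) trials — identified from the lick trains
#'   by a lick count of 3 or more in the response window — the preferred
#'   drive persists and no suppression is applied;
#' * planted lick-coupled cells spike with the animal's licking, mixing a
#'   lick-driven component into their rate with weight `lick_coupling`.
#'
#' Per bin and cell the spike is a Bernoulli draw whose log-odds combine
#' baseline, stimulus drive, and suppression.
#'
#' @param schedule A `trial_table`.
#' @param variant The [task_variant()] of the schedule.
#' @param spec A [population_spec()].
#' @param licks `lick_trains` for the same schedule; required whenever
#'   `fraction_lick_cells > 0` or the learned stage must distinguish
#'   engaged from lapse trials.
#' @param horizon Trial duration covered by the raster, seconds.
#' @param seed Integer seed.
#' @return An object of class `spike_raster`: list with `activity`
#'   (binary array cells x bins x trials), `bin_width` (1/15 s), `times`
#'   (bin onsets), `cell_flags` (logical, planted lick-cell ground truth),
#'   `stim_cells` (logical), and `stage`.
#' @export
simulate_population <- function(schedule, variant, spec, licks = NULL,
                                horizon = 4.5, seed = NULL) {
  if (!inherits(spec, "population_spec"))
    stop_validation("spec must be a population_spec object")
  if (!inherits(variant, "task_variant"))
    stop_validation("variant must be a task_variant object")
  if (spec$fraction_lick_cells > 0 && is.null(licks))
    stop_validation("licks are required when fraction_lick_cells > 0")
  if (!is.null(licks) && !all(licks$trial_id %in% schedule$trial_id))
    stop_validation("licks reference trials absent from the schedule")
  bw <- 1 / 15
  n_bins <- floor(horizon * 15)
  n_trials <- nrow(schedule)
  with_seed(seed, {
    n_cells <- spec$n_cells
    if (is.null(n_cells))
      n_cells <- as.integer(max(10, round(rnorm(1, spec$mean_cells, spec$sd_cells))))
    n_lick <- round(spec$fraction_lick_cells * n_cells)
    n_stim <- round(spec$fraction_stim_locked * n_cells)
    roles <- sample(n_cells)
    lick_cells <- roles[seq_len(n_lick)]
    stim_cells <- roles[n_lick + seq_len(min(n_stim, n_cells - n_lick))]
    is_lick <- seq_len(n_cells) %in% lick_cells
    is_stim <- seq_len(n_cells) %in% stim_cells

    times <- (seq_len(n_bins) - 1L) * bw
    ind_P <- stimulus_indicator(build_timeline(variant, "P"), bw,
                                max(horizon, build_timeline(variant, "P")$total_duration))[seq_len(n_bins)]
    ind_NP <- stimulus_indicator(build_timeline(variant, "NP"), bw,
                                 max(horizon, build_timeline(variant, "NP")$total_duration))[seq_len(n_bins)]

    lick_counts <- NULL
    if (!is.null(licks))
      lick_counts <- bin_lick_counts(licks, schedule$trial_id, bw, n_bins)
    engaged <- rep(TRUE, n_trials)
    if (spec$stage == "learned" && !is.null(lick_counts)) {
      rw <- variant$response_window
      win_bins <- which(times + bw / 2 >= rw[1] & times + bw / 2 < rw[2])
      engaged <- rowSums(lick_counts[, win_bins, drop = FALSE]) < 3
    }

    eta0 <- stats::qlogis(spec$base_p)
    sup_slope <- 1 / spec$suppression_tau
    mids <- times + bw / 2
    activity <- array(0L, dim = c(n_cells, n_bins, n_trials))
    for (tr in seq_len(n_trials)) {
      stim_tr <- schedule$stimulus[tr]
      eta <- matrix(eta0, nrow = n_cells, ncol = n_bins)
      if (spec$stage == "naive") {
        ind <- if (stim_tr == "P") ind_P else ind_NP
        eta[is_stim, ] <- eta[is_stim, ] +
          spec$naive_stim_coef * rep(ind, each = sum(is_stim))
      } else {
        eta[is_stim, ] <- eta[is_stim, ] +
          spec$stim_coef * rep(ind_P, each = sum(is_stim))
        if (stim_tr == "NP" && engaged[tr]) {
          decay <- pmax(0, mids - spec$suppression_onset) * sup_slope
          eta <- eta - rep(decay, each = n_cells)
        }
      }
      p <- stats::plogis(eta)
      if (any(is_lick)) {
        nl <- lick_counts[tr, ]
        # motor-related drive spans the lick bout at the imaging timescale:
        # full drive in frames with a lick, partial drive in adjacent
        # frames. Each cell engages with the bout on a given trial with
        # probability lick_reliability, independently across cells.
        nb <- c(0L, nl[-n_bins]) + c(nl[-1L], 0L)
        p_lickdrive <- ifelse(nl > 0, 0.9, ifelse(nb > 0, 0.45, 0.02))
        engaged_cell <- runif(sum(is_lick)) < spec$lick_reliability
        c_eff <- spec$lick_coupling * engaged_cell
        p[is_lick, ] <- (1 - c_eff) * p[is_lick, ] +
          outer(c_eff, p_lickdrive)
      }
      activity[, , tr] <- (matrix(runif(n_cells * n_bins), n_cells) < p) * 1L
    }
    structure(list(activity = activity, bin_width = bw, times = times,
                   cell_flags = is_lick, stim_cells = is_stim,
                   stage = spec$stage, trial_ids = schedule$trial_id),
              class = "spike_raster")
  })
}

#' @export
print.spike_raster <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("<spike_raster> %d cells x %d bins (%.4f s) x %d trials, stage %s\n",
              d[1], d[2], x$bin_width, d[3], x$stage))
  cat(sprintf("  planted lick cells: %d; mean activity %.4f\n",
              sum(x$cell_flags), mean(x$activity)))
  invisible(x)
}

#' Number of cells in a raster
#' @param raster A `spike_raster`.
#' @return Integer count.
#' @export
n_cells <- function(raster) dim(raster$activity)[1]

fixture_config_defaults <- function() {
  list(
    variant = "TPSD",
    stage = "naive",
    n_trials = 350L,
    ratio = 0.7,
    horizon = 4.5,
    pretrial_trials = 250L,
    profile = list(),
    population = list()
  )
}

#' Assemble a self-consistent synthetic session
#'
#' Builds one synthetic session: a trial schedule, a pretrial lick block
#' (preferred-only, rewarded — used downstream to set the individualized
#' lick threshold), session lick trains, and a spike raster, all from one
#' master seed with decoupled child streams. Trial outcomes are left
#' `"unlabeled"`; labeling is the behavior module's job
#' ([label_outcomes()]).
#'
#' @param config Named list overriding the defaults: `variant`, `stage`,
#'   `n_trials`, `ratio`, `horizon`, `pretrial_trials`, and nested
#'   `profile` / `population` argument lists passed to
#'   [behavior_profile()] and [population_spec()]. Unknown keys are an
#'   error.
#' @param seed Master integer seed.
#' @return An object of class `tpsd_fixture`: list with `variant`,
#'   `schedule`, `licks`, `pretrial_schedule`, `pretrial_licks`, `raster`,
#'   `ground_truth` (planted lick/stimulus cells, lapse trials), and
#'   `config` (full parameter echo including child seeds).
#' @export
make_fixture <- function(config = list(), seed = NULL) {
  defaults <- fixture_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_validation("unknown fixture config keys: ",
                    paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  variant <- task_variant(cfg$variant)
  profile <- do.call(behavior_profile, c(list(stage = cfg$stage), cfg$profile))
  spec <- do.call(population_spec, c(list(stage = cfg$stage), cfg$population))
  seeds <- list(schedule = child_seed(seed, 1L),
                pretrial = child_seed(seed, 2L),
                licks = child_seed(seed, 3L),
                population = child_seed(seed, 4L))

  schedule <- build_session_schedule(variant, cfg$n_trials, cfg$ratio,
                                     seed = seeds$schedule, stage = cfg$stage)
  pre_sched <- data.frame(trial_id = seq_len(cfg$pretrial_trials),
                          stimulus = "P", stage = "pretrial",
                          outcome = "unlabeled", stringsAsFactors = FALSE)
  class(pre_sched) <- c("trial_table", "data.frame")
  # pretrial animals are trained to lick reliably (>80% of trials)
  pre_profile <- behavior_profile("naive",
                                  base_rate = profile$base_rate,
                                  stim_gain_P = profile$stim_gain_P,
                                  baseline_rate = profile$baseline_rate,
                                  reward_gain = profile$reward_gain,
                                  respond_prob = 0.9)
  pretrial_licks <- simulate_licking(pre_sched, variant, pre_profile,
                                     horizon = cfg$horizon,
                                     seed = seeds$pretrial)
  licks <- simulate_licking(schedule, variant, profile,
                            horizon = cfg$horizon, seed = seeds$licks)
  raster <- simulate_population(schedule, variant, spec, licks = licks,
                                horizon = cfg$horizon, seed = seeds$population)
  structure(list(
    variant = variant,
    schedule = schedule,
    licks = licks,
    pretrial_schedule = pre_sched,
    pretrial_licks = pretrial_licks,
    raster = raster,
    ground_truth = list(lick_cells = which(raster$cell_flags),
                        stim_cells = which(raster$stim_cells),
                        lapse_trials = which(attr(licks, "lapse"))),
    config = c(cfg, list(seed = seed, child_seeds = seeds,
                         profile_used = unclass(profile),
                         population_used = unclass(spec)))
  ), class = "tpsd_fixture")
}

#' Write a fixture bundle to plain-text files
#'
#' Serializes a [make_fixture()] bundle into a directory of delimited and
#' JSON files: trial tables as TSV, lick trains as TSV with integer 250 Hz
#' tick indices (lossless), the raster as sparse nonzero triplets plus a
#' JSON side-car with dimensions and cell flags, and the full config echo
#' as JSON.
#'
#' @param fixture A `tpsd_fixture`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(fixture, dir) {
  if (!inherits(fixture, "tpsd_fixture"))
    stop_validation("fixture must be a tpsd_fixture")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(as.data.frame(fixture$schedule), "trials.tsv")
  tsv(as.data.frame(fixture$pretrial_schedule), "pretrial_trials.tsv")
  lick_df <- function(lk) data.frame(trial_id = lk$trial_id,
                                     tick = as.integer(round(lk$time * 250)))
  tsv(lick_df(fixture$licks), "licks.tsv")
  tsv(lick_df(fixture$pretrial_licks), "pretrial_licks.tsv")
  nz <- which(fixture$raster$activity != 0L, arr.ind = TRUE)
  colnames(nz) <- c("cell", "bin", "trial")
  tsv(as.data.frame(nz), "raster.tsv")
  meta <- list(
    dims = dim(fixture$raster$activity),
    bin_width = fixture$raster$bin_width,
    stage = fixture$raster$stage,
    trial_ids = fixture$raster$trial_ids,
    cell_flags = fixture$raster$cell_flags,
    stim_cells = fixture$raster$stim_cells,
    horizon = attr(fixture$licks, "horizon"),
    respond = attr(fixture$licks, "respond"),
    lapse = attr(fixture$licks, "lapse"),
    schedule_ratio = attr(fixture$schedule, "ratio"),
    variant = fixture$variant$name
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fixture$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir Directory containing the serialized bundle.
#' @return A `tpsd_fixture` equivalent to the one written.
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  variant <- task_variant(meta$variant)
  rd <- function(f) read.table(file.path(dir, f), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  schedule <- rd("trials.tsv")
  attr(schedule, "ratio") <- meta$schedule_ratio
  attr(schedule, "variant") <- meta$variant
  class(schedule) <- c("trial_table", "data.frame")
  pre_sched <- rd("pretrial_trials.tsv")
  class(pre_sched) <- c("trial_table", "data.frame")
  licks_from <- function(f, respond = NULL, lapse = NULL) {
    d <- rd(f)
    out <- data.frame(trial_id = d$trial_id, time = (d$tick) / 250)
    attr(out, "horizon") <- meta$horizon
    attr(out, "clock_hz") <- 250L
    if (!is.null(respond)) attr(out, "respond") <- respond
    if (!is.null(lapse)) attr(out, "lapse") <- lapse
    class(out) <- c("lick_trains", "data.frame")
    out
  }
  licks <- licks_from("licks.tsv", respond = meta$respond, lapse = meta$lapse)
  pre_licks <- licks_from("pretrial_licks.tsv")
  nz <- rd("raster.tsv")
  activity <- array(0L, dim = meta$dims)
  activity[cbind(nz$cell, nz$bin, nz$trial)] <- 1L
  raster <- structure(list(
    activity = activity, bin_width = meta$bin_width,
    times = (seq_len(meta$dims[2]) - 1L) * meta$bin_width,
    cell_flags = meta$cell_flags, stim_cells = meta$stim_cells,
    stage = meta$stage, trial_ids = meta$trial_ids
  ), class = "spike_raster")
  structure(list(
    variant = variant, schedule = schedule, licks = licks,
    pretrial_schedule = pre_sched, pretrial_licks = pre_licks,
    raster = raster,
    ground_truth = list(lick_cells = which(meta$cell_flags),
                        stim_cells = which(meta$stim_cells),
                        lapse_trials = which(meta$lapse)),
    config = cfg
  ), class = "tpsd_fixture")
}
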