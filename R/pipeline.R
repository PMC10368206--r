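pipeline_config_defaults <- function() {
  list(
    variant = "TPSD",
    stage = "learned",
    n_trials = 350L,
    ratio = 0.7,
    horizon = 4.5,
    pretrial_trials = 250L,
    window = 150L,
    profile = list(),
    population = list(),
    decoding = list(n_machines = 1000L, bin_width = 0.067, horizon = 2),
    lickcells = list(n_machines = 20L, n_select = 20L),
    dynamics = list(n_iter = 1000L),
    stages = c("simulate", "behavior", "lickcells", "decode", "dynamics")
  )
}

#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Two presets are
#' provided: `"demo"` (10 cells, 60 trials, 50 machines — a desk-scale
#' smoke run) and `"paper-scale"` (full session sizes: 350 trials, drawn
#' population size, 10000 lick machines and 1000 imaging machines per
#' bin). Any field can be overridden; unknown keys are rejected before
#' any computation.
#'
#' @param preset `"demo"` or `"paper-scale"`.
#' @param ... Named overrides of the default fields (nested lists such as
#'   `decoding` are merged field-wise).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("demo", "paper-scale"), ...) {
  preset <- match.arg(preset)
  cfg <- pipeline_config_defaults()
  if (preset == "demo") {
    cfg$n_trials <- 60L
    cfg$ratio <- 0.5
    cfg$pretrial_trials <- 30L
    cfg$window <- 40L
    cfg$population <- list(n_cells = 10L)
    cfg$decoding$n_machines <- 50L
    cfg$lickcells <- list(n_machines = 2L, n_select = 5L)
    cfg$dynamics$n_iter <- 200L
  } else {
    cfg$decoding$n_machines <- 10000L
    cfg$lickcells$n_machines <- 1000L
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop_validation("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) {
    bad <- if (is.list(cfg[[nm]]) && nm %in% c("decoding", "lickcells", "dynamics"))
      setdiff(names(overrides[[nm]]), names(pipeline_config_defaults()[[nm]]))
    else character(0)
    if (length(bad))
      stop_validation("unknown config keys in ", nm, ": ",
                      paste(bad, collapse = ", "))
  }
  cfg <- modifyList(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> threshold/label -> behavioral metrics ->
#' lick-cell removal -> decoding -> dynamics on a synthetic session,
#' writing every table, a machine-readable summary and a manifest with
#' content hashes to `out_dir`. Identical `config` + `seed` reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param seed Master integer seed.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing and returns results only.
#' @return Invisibly, a list with the fixture, labeled outcomes, metrics,
#'   flagged cells, decoding curves, dynamics results and the `summary`
#'   list.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("config must come from pipeline_config()")
  variant <- task_variant(config$variant)

  fx <- run_stage("simulate", make_fixture(
    config = list(variant = config$variant, stage = config$stage,
                  n_trials = config$n_trials, ratio = config$ratio,
                  horizon = config$horizon,
                  pretrial_trials = config$pretrial_trials,
                  profile = config$profile, population = config$population),
    seed = child_seed(seed, 10L)))

  res <- run_stage("behavior", {
    pre_rates <- window_lick_rates(fx$pretrial_schedule, fx$pretrial_licks,
                                   variant$response_window)
    threshold <- lick_threshold(pre_rates)
    outcomes <- label_outcomes(fx$schedule, fx$licks, threshold,
                               variant$response_window)
    best <- best_window_dprime(outcomes, window = config$window)
    probs <- lick_probability_profile(fx$licks, outcomes,
                                      group_by = c("stage", "stimulus", "outcome"))
    list(threshold = threshold, outcomes = outcomes, best = best,
         probabilities = probs)
  })

  lick_res <- NULL
  raster_clean <- fx$raster
  if ("lickcells" %in% config$stages) {
    lick_res <- run_stage("lickcells", {
      tab <- score_cells(fx$raster, res$outcomes,
                         response_window = variant$response_window,
                         n_select = config$lickcells$n_select,
                         n_machines = config$lickcells$n_machines,
                         seed = child_seed(seed, 20L))
      adm <- admit_session(tab)
      flagged <- flag_lick_cells(tab, adm)
      list(table = tab, admitted = isTRUE(as.logical(adm)),
           r = attr(adm, "r"), p = attr(adm, "p"), flagged = flagged)
    })
    if (length(lick_res$flagged))
      raster_clean <- remove_cells(fx$raster, lick_res$flagged)
  }

  decode_res <- NULL
  if ("decode" %in% config$stages) {
    decode_res <- run_stage("decode", {
      feats <- bin_features(fx$licks, trial_ids = fx$schedule$trial_id,
                            bin_width = config$decoding$bin_width,
                            horizon = config$decoding$horizon)
      curve <- bootstrap_svm_curve(feats, fx$schedule$stimulus,
                                   n_machines = config$decoding$n_machines,
                                   seed = child_seed(seed, 30L))
      control <- shuffled_control(feats, fx$schedule$stimulus,
                                  n_machines = config$decoding$n_machines,
                                  seed = child_seed(seed, 31L))
      list(lick_stimulus = list(curve = curve, control = control))
    })
  }

  dyn_res <- NULL
  if ("dynamics" %in% config$stages) {
    dyn_res <- run_stage("dynamics", {
      p_trials <- res$outcomes$trial_id[res$outcomes$stimulus == "P"]
      np_trials <- res$outcomes$trial_id[res$outcomes$stimulus == "NP"]
      summ_P <- bootstrap_mean_activity(raster_clean, p_trials,
                                        n_iter = config$dynamics$n_iter,
                                        seed = child_seed(seed, 40L))
      summ_NP <- bootstrap_mean_activity(raster_clean, np_trials,
                                         n_iter = config$dynamics$n_iter,
                                         seed = child_seed(seed, 41L))
      ind <- stimulus_indicator(build_timeline(variant, "P"),
                                raster_clean$bin_width,
                                horizon = config$horizon)[seq_along(raster_clean$times)]
      corr <- stimulus_correlation(summ_P, ind)
      p_period <- c(0, build_timeline(variant, "P")$total_duration)
      pt <- list(P = peak_times(raster_clean, p_trials, p_period),
                 NP = peak_times(raster_clean, np_trials, p_period))
      ks <- compare_peak_distributions(pt)
      traj <- outcome_trajectories(raster_clean, res$outcomes)
      div <- list()
      for (pr in list(c("Hit", "CR"), c("Hit", "FA"), c("CR", "FA")))
        if (all(pr %in% names(traj$trajectories)))
          div[[paste(pr, collapse = "_vs_")]] <-
            trajectory_divergence(traj, pr[1], pr[2])
      list(mean_activity = list(P = summ_P, NP = summ_NP),
           stimulus_correlation = corr, peak_times = pt, ks = ks,
           trajectories = traj, divergence = div)
    })
  }

  summary <- list(
    seed = seed,
    stage = config$stage,
    n_trials = config$n_trials,
    n_cells = n_cells(fx$raster),
    threshold = res$threshold,
    dprime = res$best$dprime,
    hit_rate = res$best$hit_rate,
    cr_rate = res$best$cr_rate,
    window_start = res$best$window_start,
    n_flagged_cells = if (is.null(lick_res)) NA_integer_
                      else length(lick_res$flagged),
    peak_lick_decoding = if (is.null(decode_res)) NA_real_
                         else max(decode_res$lick_stimulus$curve$mean_acc),
    stimulus_correlation_r = if (is.null(dyn_res)) NA_real_
                             else dyn_res$stimulus_correlation$r,
    divergence = if (is.null(dyn_res)) NULL else dyn_res$divergence
  )

  out <- list(fixture = fx, behavior = res, lickcells = lick_res,
              decoding = decode_res, dynamics = dyn_res,
              summary = summary, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(as.data.frame(out$behavior$outcomes), "outcomes.tsv")
  tsv(as.data.frame(out$behavior$probabilities), "lick_probabilities.tsv")
  if (!is.null(out$lickcells))
    tsv(as.data.frame(out$lickcells$table), "cell_scores.tsv")
  if (!is.null(out$decoding)) {
    cv <- out$decoding$lick_stimulus
    d <- data.frame(time = cv$curve$time,
                    mean_acc = cv$curve$mean_acc,
                    lo = cv$curve$lo, hi = cv$curve$hi,
                    control_mean = cv$control$mean_acc,
                    control_lo = cv$control$lo,
                    control_hi = cv$control$hi)
    tsv(d, "decoding_lick_stimulus.tsv")
  }
  if (!is.null(out$dynamics)) {
    for (s in names(out$dynamics$mean_activity))
      tsv(as.data.frame(out$dynamics$mean_activity[[s]]),
          paste0("mean_activity_", s, ".tsv"))
    tsv(out$dynamics$ks, "peak_time_ks.tsv")
  }
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}
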