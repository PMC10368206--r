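#' Task variant definitions for the TPSD paradigms
#'
#' Constructs the parameter set of one variant of the go/no-go temporal
#' pattern sensory discrimination (TPSD) task. Each variant presents two
#' rhythmic audiovisual patterns that differ only in the temporal structure
#' of their intra-trial stimuli:
#'
#' * `"TPSD"` — preferred (P): four 0.2 s stimuli; nonpreferred (NP): four
#'   0.9 s stimuli; 0.2 s gaps; water reward at 1.2 s; response window
#'   1–2 s; time-out 6.5–8 s; inter-trial interval 4 s.
#' * `"TPSD_mod"` — the duration-matched paradigm with the long stimulus as
#'   the rewarded pattern: P is three 0.733 s stimuli, NP is seven 0.2 s
#'   stimuli, so both patterns span the same total time; reward at 2.3 s;
#'   response window 2–3.2 s.
#' * `"control"` — identical trial schedule and timing to `"TPSD"` but the
#'   monitor and speaker are off, so the stimulus indicator is all-zero.
#'
#' All times are in seconds, measured from the first stimulus onset of the
#' trial (t = 0).
#'
#' @param name One of `"TPSD"`, `"TPSD_mod"`, `"control"`.
#' @return An object of class `task_variant`: a list with elements
#'   `name`, `patterns` (per-stimulus `n_intra` and `stim_dur`), `gap_dur`,
#'   `reward_time`, `response_window`, `timeout_range`, `iti`, and
#'   `stimulus_on` (`FALSE` for the control variant).
#' @examples
#' v <- task_variant("TPSD")
#' build_timeline(v, "P")$total_duration   # 1.4
#' @export
task_variant <- function(name = c("TPSD", "TPSD_mod", "control")) {
  name <- match.arg(name)
  base <- switch(name,
    TPSD = , control = list(
      patterns = list(
        P  = list(n_intra = 4L, stim_dur = 0.2),
        NP = list(n_intra = 4L, stim_dur = 0.9)
      ),
      gap_dur = 0.2,
      reward_time = 1.2,
      response_window = c(1, 2),
      timeout_range = c(6.5, 8),
      iti = 4
    ),
    TPSD_mod = list(
      patterns = list(
        P  = list(n_intra = 3L, stim_dur = 0.733),
        NP = list(n_intra = 7L, stim_dur = 0.2)
      ),
      gap_dur = 0.2,
      reward_time = 2.3,
      response_window = c(2, 3.2),
      timeout_range = c(6.5, 8),
      iti = 4
    )
  )
  structure(c(list(name = name), base,
              list(stimulus_on = !identical(name, "control"))),
            class = "task_variant")
}

#' @export
print.task_variant <- function(x, ...) {
  cat("<task_variant>", x$name, "\n")
  for (s in names(x$patterns)) {
    p <- x$patterns[[s]]
    cat(sprintf("  %-2s: %d x %.3f s stimuli, %.1f s gaps\n",
                s, p$n_intra, p$stim_dur, x$gap_dur))
  }
  cat(sprintf("  reward %.1f s, response window [%.1f, %.1f] s%s\n",
              x$reward_time, x$response_window[1], x$response_window[2],
              if (!x$stimulus_on) ", stimulus OFF (control)" else ""))
  invisible(x)
}

#' Build the stimulus timeline of one pattern
#'
#' Lays out the on-epochs of a rhythmic pattern: `n_intra` stimuli of
#' `stim_dur` seconds, alternating with `gap_dur` gaps, starting and ending
#' with a stimulus. There is no leading gap, so the total duration is
#' `n_intra * stim_dur + (n_intra - 1) * gap_dur` (1.4 s for TPSD preferred,
#' 4.2 s for TPSD nonpreferred, 2.6 s for both TPSD_mod patterns).
#'
#' @param variant A [task_variant()].
#' @param stimulus `"P"` (preferred/rewarded) or `"NP"` (nonpreferred).
#' @return An object of class `stimulus_timeline`: a list with `epochs`
#'   (data frame of `onset`/`offset` of each on-epoch), `total_duration`,
#'   `stimulus`, `variant`, and `stimulus_on`.
#' @export
build_timeline <- function(variant, stimulus = c("P", "NP")) {
  if (!inherits(variant, "task_variant"))
    stop_validation("variant must be a task_variant object")
  stimulus <- match.arg(stimulus)
  p <- variant$patterns[[stimulus]]
  onsets <- (seq_len(p$n_intra) - 1L) * (p$stim_dur + variant$gap_dur)
  epochs <- data.frame(onset = onsets, offset = onsets + p$stim_dur)
  structure(list(
    epochs = epochs,
    total_duration = p$n_intra * p$stim_dur + (p$n_intra - 1L) * variant$gap_dur,
    stimulus = stimulus,
    variant = variant$name,
    stimulus_on = variant$stimulus_on
  ), class = "stimulus_timeline")
}

#' Binary stimulus on/off indicator on a time grid
#'
#' Discretizes a [build_timeline()] result onto half-open bins
#' `[t, t + bin_width)`: a bin is 1 when its midpoint falls inside an
#' on-epoch, 0 otherwise. Control-variant timelines yield an all-zero
#' vector regardless of their nominal epochs.
#'
#' @param timeline A `stimulus_timeline`.
#' @param bin_width Bin width in seconds (> 0).
#' @param horizon Total duration covered, in seconds; must be at least the
#'   timeline's `total_duration`. The vector has `ceiling(horizon/bin_width)`
#'   entries.
#' @return Integer vector of 0/1.
#' @export
stimulus_indicator <- function(timeline, bin_width, horizon) {
  if (!inherits(timeline, "stimulus_timeline"))
    stop_validation("timeline must be a stimulus_timeline object")
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  assert_scalar_number(horizon, "horizon")
  if (horizon < timeline$total_duration - 1e-9)
    stop_validation("horizon must cover the full timeline (",
                    timeline$total_duration, " s)")
  n <- ceiling(horizon / bin_width)
  mids <- (seq_len(n) - 0.5) * bin_width
  if (!timeline$stimulus_on) return(integer(n))
  on <- vapply(mids, function(m)
    any(m >= timeline$epochs$onset & m < timeline$epochs$offset), logical(1))
  as.integer(on)
}

#' Randomized trial schedule for one session
#'
#' Draws a session of `n_trials` trials with an exact preferred-trial count
#' of `round(n_trials * ratio)` (half-up), in randomized order. The main
#' task uses a 7:3 preferred/nonpreferred ratio (sessions of 350 trials
#' after a first session of 250); a 6:4 ratio session probes ratio
#' dependence.
#'
#' @param variant A [task_variant()].
#' @param n_trials Number of trials (> 0).
#' @param ratio Preferred-trial fraction, strictly between 0 and 1.
#' @param seed Integer seed for the trial-order permutation; the same seed
#'   reproduces the same schedule.
#' @param stage Session stage label: `"naive"`, `"learned"`, or `"pretrial"`.
#' @return A `trial_table`: a data frame with columns `trial_id`,
#'   `stimulus` (`"P"`/`"NP"`), `stage`, `outcome` (initially
#'   `"unlabeled"`; see [label_outcomes()]), and attributes `ratio` and
#'   `variant`.
#' @export
build_session_schedule <- function(variant, n_trials, ratio = 0.7, seed = NULL,
                                   stage = c("naive", "learned", "pretrial")) {
  if (!inherits(variant, "task_variant"))
    stop_validation("variant must be a task_variant object")
  stage <- match.arg(stage)
  assert_scalar_number(n_trials, "n_trials", positive = TRUE)
  assert_scalar_number(ratio, "ratio")
  if (ratio <= 0 || ratio >= 1) stop_validation("ratio must be in (0, 1)")
  n_trials <- as.integer(n_trials)
  n_p <- as.integer(round_half_up(n_trials * ratio))
  stim <- c(rep("P", n_p), rep("NP", n_trials - n_p))
  stim <- with_seed(seed, sample(stim))
  out <- data.frame(
    trial_id = seq_len(n_trials),
    stimulus = stim,
    stage = stage,
    outcome = "unlabeled",
    stringsAsFactors = FALSE
  )
  attr(out, "ratio") <- ratio
  attr(out, "variant") <- variant$name
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Total stimulus exposure per stimulus type
#'
#' Seconds of pattern presentation accumulated over a schedule:
#' `count(type) * total_duration(type)`. In a 350-trial 60:40 TPSD session
#' this is 294 s for the preferred and 588 s for the nonpreferred pattern —
#' the asymmetry that motivates keeping more preferred trials.
#'
#' @param schedule A `trial_table`.
#' @param variant The [task_variant()] the schedule was built for.
#' @return Named numeric vector `c(P = , NP = )`, in seconds.
#' @export
total_stimulus_exposure <- function(schedule, variant) {
  if (!inherits(variant, "task_variant"))
    stop_validation("variant must be a task_variant object")
  durs <- vapply(c("P", "NP"), function(s)
    build_timeline(variant, s)$total_duration, numeric(1))
  counts <- vapply(c("P", "NP"), function(s)
    sum(schedule$stimulus == s), numeric(1))
  counts * durs
}
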