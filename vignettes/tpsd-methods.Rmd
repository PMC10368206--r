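---
title: "Methods: behavioral and population-dynamics analysis of temporal pattern discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and population-dynamics analysis of temporal pattern discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsd)
```

## The task and its timing model

The temporal pattern sensory discrimination (TPSD) task is a go/no-go
paradigm for head-fixed mice in which the two alternatives differ *only in
temporal structure*: the rewarded (preferred, P) pattern is four 0.2 s
audiovisual stimuli, the unrewarded (nonpreferred, NP) pattern is four
0.9 s stimuli, both with 0.2 s gaps. Because there is no leading gap, the
patterns span `4*0.2 + 3*0.2 = 1.4` s and `4*0.9 + 3*0.2 = 4.2` s. Water
arrives at 1.2 s on preferred trials and licks count toward the decision in
the 1–2 s response window; an incorrect response triggers a 6.5–8 s
time-out, and trials are separated by a 4 s inter-trial interval. The
duration-matched variant (`TPSD_mod`) inverts the contingency (three
733 ms stimuli rewarded vs seven 200 ms stimuli) so that both patterns
span the same 2.6 s, with reward at 2.3 s and a 2–3.2 s response window.
A control variant keeps the schedule but turns the stimulus off.

All times are trial-relative (t = 0 at first stimulus onset). Timelines
are discretized on half-open bins `[t, t + delta)` with membership decided
by the bin midpoint — an unambiguous convention that reproduces the
analytic on-times to within half a bin per epoch edge. We assume no gap
precedes the first stimulus; only then do the printed durations
(1.4 / 4.2 / 2.6 s) come out exactly. Preferred-trial counts in a
schedule are `round(n * ratio)` (half-up; the convention is not critical
and is stated for reproducibility).

## Behavioral metrics

Outcomes follow the usual go/no-go taxonomy (Hit/Miss on preferred,
FA/CR on nonpreferred). A trial counts as a response when the mean lick
rate over the response window reaches the animal's individualized
threshold — the mean of its last pretrial session's per-trial lick rates
minus one sample SD, floored at zero. The averaging window for the rate
is the response window itself; the threshold criterion is stated as a
rate, and the response window is the natural support. Units are licks/s
throughout.

Discriminability is
`d' = qnorm(hit fraction) - qnorm(false-alarm fraction)`, with rates of
exactly 1 and 0 replaced by 0.99 and 0.01 before the transform so the
index stays finite; no other continuity correction is applied, so
`|d'| <= 2 * qnorm(0.99) ~ 4.65`. Session performance is the maximum d'
over a sliding 150-trial window (ties to the earliest window); hit and CR
rates are reported for that same best window, and d' = 2 serves as the
learning threshold. Lick-probability profiles bin licks into 0.1 s
windows, compute the per-animal probability of at least one lick per bin,
and average *across animals*, never across pooled trials; groups that are
empty (in practice Miss trials in trained animals) are dropped.

## Time-resolved decoding

Decoding asks *when* in the trial the behavior or the population carries
stimulus or outcome information. Features are built per 0.067 s bin —
the lick count (one feature) or each cell's binary deconvolved-spike
value (one feature per cell; the 15 Hz imaging bins map one-to-one onto
the decoding bins). The bin count is `floor(horizon / bin_width)`; a
final partial bin is dropped. Per bin we train many support-vector
machines with an RBF kernel, each on a freshly drawn stratified 80/20
train/test split, and keep the held-out accuracies as a per-bin
distribution ("bootstrap" here means resampling the split, not the
trials; a resample-with-replacement variant would be a one-line change
but is not what the accuracy distributions describe). Every decoding run
is paired with a shuffled-label control in which each machine sees an
independently permuted copy of the labels; a curve is read against the
control band, not against the nominal 0.5. Chance is exactly 0.5 only
for balanced classes, which is why the package's synthetic decoding
checks use balanced schedules while the task itself runs 7:3.

Untuned machines use box constraint 1 and the median pairwise-distance
heuristic for the kernel scale (which also makes accuracy invariant to
positive rescaling of the features). For full-network neural decoding,
`tune_hyperparameters()` searches cost and kernel scale over a log-scaled
space under stratified 5-fold cross-validation; the first candidate is
always the default pair, so a budget of 1 reproduces the untuned
machine. The single-feature lick decoder is run untuned. Bins whose
features are constant across trials cannot be separated and are recorded
at chance with a warning rather than fitted.

`kcell_selection_curve()` adds forward sequential feature selection:
per bin and machine, cells are added greedily, each addition scored by
held-out accuracy on an internal split of the training trials, until k
cells are chosen; the final k-cell machine is then scored on the outer
test set. The per-bin, per-cell selection tally divided by the
`k * n_machines` possible selection slots gives the selection map; when
k equals the population size every cell occupies `1/k` of the slots by
construction. Two numerical choices matter here. First, candidate
evaluations use a 50/50 internal split — with the discrete accuracies of
small validation sets, a larger validation half buys finer granularity,
which is what lets genuinely informative cells keep winning steps — and
the cheap `1/dim` kernel-scale default (the final machine uses the
median heuristic). Second, exact ties between candidates are broken *at
random*. With binary per-bin features exact ties are pervasive, and any
deterministic preference (say, lowest cell index) turns the selection
counts into a position artifact that corrupts every analysis built on
them; randomized tie-breaking restores exchangeability of uninformative
cells.

## Lick-modulated cells

Movement-related activity rides on sensory activity in cortical
recordings, so cells coupled to licking are identified and removed
before sensory analyses. Trials are split into a lick group (Hit + FA)
and a no-lick group (CR + Miss): within the response window, stimuli and
reward are heterogeneous *within* each group, so the only systematic
between-group difference is licking. Per response-window bin and
machine, forward selection picks the 20 most predictive cells
(`n_select` clamps to the population size); every selected cell accrues
the machine's z-scored accuracy, so sub-chance machines punish their
cells and chance machines contribute nothing. The z-score is referenced
to the spread of that bin's shuffled-label control accuracies, centered
at exactly 0.5 so the sign convention is exact; at least 20 control
machines are always run so the spread estimate is stable even when few
scoring machines are requested. Sessions are admitted only when total
score and selection count correlate positively and significantly
(Pearson, alpha 0.05) — the signature of reliable predictability — and
within an admitted session, cells whose total score exceeds the mean by
more than one SD are flagged. An empty flag set is a legitimate outcome.
Scores accumulate within a session; they are never summed across
sessions. Whether the 20-cell selection repeats per machine or once per
bin is ambiguous on its face; the package selects per machine (each
machine's split yields its own 20 cells), which makes the selection count
a graded reliability measure rather than a 0/15 indicator.

## Network dynamics

`bootstrap_mean_activity()` resamples trials with replacement (1000
iterations by default; cells are never resampled, since the population
is the object of inference, not a sample) and averages the binary
activity over cells and trials per bin; per-animal iteration curves can
be pooled into one grand distribution, and bands are percentile
intervals. The correlation of activity with the stimulus is the Pearson
correlation between the pooled (iteration x bin) activity values and the
0/1 stimulus indicator on the same grid, with the analytic p-value;
whether one pools bins across iterations or animals first is not
determined by the method's description, and the package pools
(iteration x bin) pairs.

Peak-time distributions take, per cell, the time of maximum
*trial-averaged* activity within a stated period (ties to the earliest
bin); their CDFs are compared by two-sample KS tests with the family
alpha Bonferroni-divided by the number of pairs (0.0083 for six pairs,
0.0167 for three), exact p-values below 30 samples and asymptotic
otherwise. Heatmap ordering sorts cells by peak bin, groups ascending,
within-group by cell index. Neural trajectories average each cell over
trials within each outcome, fit a PCA across the concatenated
(outcome x bin) observations with per-cell centering and no variance
scaling (the data are already on a common binary-rate scale), and keep
the first three components; the divergence between two outcomes is the
mean Euclidean distance between their component trajectories over bins.

## The synthetic-data generator

No recordings ship with the package, so a generator produces sessions
with the statistical structure the analyses assume. Its defaults are
fixed choices, documented here, not claims about any particular animal.

**Licking** is an inhomogeneous Bernoulli process on the 250 Hz lickport
clock with a per-trial *respond* decision, because real licking is
bouty: an engaged trial licks at 4 licks/s early, ramps to 8 licks/s
(gain 2) from 0.5 s, adds a 1.5x consumption boost between water and
vacuum on rewarded trials, and returns to the sparse 0.5 licks/s
baseline after the window; a non-respond trial stays at baseline. Naive
animals respond on 55% of trials regardless of the stimulus — before the
reward, naive licking carries no stimulus information, which is the
naive decoding null. Learned animals respond on 97% of preferred trials
and lapse on 12% of nonpreferred trials (the false alarms); engaged
nonpreferred trials begin at 4 licks/s and are exponentially suppressed
from 0.7 s (time constant 0.3 s) — 0.7 s being the time at which
behavior and network activity diverge with learning. Pretrial sessions
(preferred-only, every trial rewarded) use a 90% respond probability,
matching the >80% licking criterion that gates task entry.

**Spiking** is Bernoulli per 1/15 s bin and cell with logistic rate:
baseline probability 0.08/bin; stimulus-locked cells (30% by default)
get +0.4 logits during on-epochs of the *presented* pattern when naive
(weak untuned sensory response) and +1.2 logits locked to the
*preferred* pattern on all trials when learned (predictive coding of the
rewarded rhythm); on learned nonpreferred trials where the animal
withheld licking (fewer than 3 response-window licks), every cell's
log-odds decay linearly from 0.7 s (slope 1/0.45 per second) — network
suppression; on lapse trials the predictive drive persists unsuppressed,
which is what clusters Hit with FA and separates both from CR in
trajectories and outcome decoding. Planted lick cells (10%) mix a
lick-driven component into their rate with weight `lick_coupling`: full
drive (p = 0.9) in frames containing a lick, partial drive (0.45) in
adjacent frames — motor-related activity spans the lick bout at the
imaging timescale, much as calcium deconvolution smears spike timing —
and near-silence (0.02) elsewhere; each cell engages with a given
trial's bout with probability 0.8, independently across cells, since
perfectly redundant lick cells would be statistically indistinguishable
from one cell and unrecoverable in principle. Population size, when not
stated, is drawn from a normal with mean 108 and SD 39.2 (truncated at
10), the across-animal field-of-view statistics the generator emulates.

What the generator deliberately omits: calcium indicator kinetics (the
pipeline consumes deconvolved spikes), locomotion and pupil covariates,
inter-trial-interval structure, electrode/optical artifacts, and any
slow drift across a session. Consequently, passing tests demonstrate
that the *analysis* recovers planted structure under the stated
statistical assumptions — not that real cortical data satisfy those
assumptions.

## Problem sizes and numerical choices

The package's checks run at desk scale by choice: decoding checks use
200-trial balanced sessions with 100 machines per bin; lick-cell
recovery uses 60-cell populations with 60-trial sessions, one scoring
machine per response-window bin (plus the >= 20 control machines that
stabilize the z reference), aggregated over 20 generator seeds;
trajectory and peak-time checks use 40-cell, 160-trial sessions; the
bootstrap-coverage check uses 200 replicates of 8-cell, 30-trial
sessions at 300 iterations. Reference-scale runs (10000 lick machines,
1000 imaging machines, 1000 bootstrap iterations) are available through
`pipeline_config("paper-scale")`. Every random step takes an explicit
seed; `make_fixture()` and `run_pipeline()` derive decoupled child
streams from one master seed and echo them into their outputs.

Degenerate inputs are handled explicitly rather than incidentally:
constant-feature bins decode at 0.5 with a warning; zero-variance cells
are never selected on merit; constant score tables are not admitted;
rank-deficient trajectory input returns fewer components with a warning;
zero-variance correlation input is an error, as the coefficient is
undefined.

## Known limitations

The lick/no-lick grouping removes the licking confound only insofar as
outcomes are mixed within groups; in a strongly learned session where
FA and Miss are rare the groups nearly coincide with the stimulus split,
and stimulus-locked cells can leak into the flag set. The d' windowing
maximizes over windows and is therefore upward-biased for short
sessions. Percentile bootstrap bands slightly undercover at small trial
counts. Multiclass outcome decoding is implemented pairwise only, and
dimensionality reduction is PCA only.
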