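# tpsd

Analysis toolkit for **temporal pattern sensory discrimination (TPSD)**
experiments: go/no-go tasks in which head-fixed mice discriminate two
rhythmic audiovisual patterns that differ only in their temporal structure
(four 0.2 s stimuli vs four 0.9 s stimuli, 0.2 s gaps), while licking is
recorded at 250 Hz and V1 layer-2/3 populations are imaged at 15 Hz. The
package is written for behavioral and systems neuroscientists who want the
full analysis chain — from trial schedules, lick trains and deconvolved
spike rasters to learning curves, time-resolved decoding and
state-space trajectories — as tested, reusable functions rather than
one-off scripts.

## What it computes

* **Task model** — stimulus timelines and binary on/off indicators for the
  TPSD, duration-matched (`TPSD_mod`) and stimulus-off control variants;
  randomized trial schedules at exact P/NP ratios; stimulus-exposure
  accounting.
* **Behavior** — outcome labeling against an individualized lick-rate
  threshold (last pretrial session mean − 1 SD); the discriminability
  index `d′ = Φ⁻¹(Hr) − Φ⁻¹(FAr)` with 0/1 rates clipped to 0.01/0.99;
  best sliding 150-trial-window d′ with matched hit/CR rates; per-animal
  lick-probability profiles in 0.1 s bins.
* **Decoding** — per-0.067 s-bin bootstrapped RBF-SVM decoding of stimulus
  or trial outcome from licking or population spiking (resampled
  stratified 80/20 splits), always paired with shuffled-label controls;
  5-fold cross-validated hyperparameter search; forward sequential
  selection of k cells with per-bin selection maps.
* **Lick-modulated cells** — the selection-scoring-admission algorithm
  that isolates motor/decision-coupled cells (Hit+FA vs CR+Miss within
  the response window, 20-cell forward selection, z-scored accuracy
  scores, positive-significant score/count correlation as the admission
  gate, mean + 1 SD flagging) and their removal before sensory analyses.
* **Dynamics** — trial-resampling bootstrap of mean network activity with
  percentile bands (1000 iterations); Pearson correlation of activity
  with the stimulus indicator; per-cell peak-activity-time distributions
  with Bonferroni-corrected two-sample KS comparisons; time-sorted
  heatmap orderings; outcome-conditioned PCA trajectories with a scalar
  divergence metric.
* **Synthetic data** — a generator for lick trains (bouty, per-trial
  respond decisions; learned suppression of nonpreferred licking from
  0.7 s) and binary spike rasters (stimulus-locked drive, learned network
  suppression, planted lick-coupled cells with ground-truth flags), so
  every stage is testable without recordings.

## Worked example

A desk-scale end-to-end run on a synthetic learned session (10 cells, 60
trials, 50 machines per bin):

```r
library(tpsd)
cfg <- pipeline_config("demo")
out <- run_pipeline(cfg, seed = 5, out_dir = "demo_run")
str(out$summary)
#> List of 13
#>  $ seed                  : num 5
#>  $ stage                 : chr "learned"
#>  $ n_trials              : int 60
#>  $ n_cells               : int 10
#>  $ threshold             : num 5.59
#>  $ dprime                : num 2.93
#>  $ hit_rate              : num 0.947
#>  $ cr_rate               : num 0.905
#>  $ window_start          : int 4
#>  $ n_flagged_cells       : int 1
#>  $ peak_lick_decoding    : num 0.872
#>  $ stimulus_correlation_r: num 0.484
#>  ...
```

Reading the numbers: the individualized lick threshold came out at 5.59
licks/s; the best 40-trial window of this learned session reaches
d′ = 2.93 (above the d′ = 2 learning threshold) with a 95% hit rate and a
90% correct-rejection rate; the lick-cell stage flagged exactly one cell
(the one planted lick-coupled cell — `out$lickcells$flagged` equals
`out$fixture$ground_truth$lick_cells`); lick-based stimulus decoding
peaks at 87% accuracy; and the bootstrapped mean activity of the cleaned
population correlates positively (r = 0.48) with the preferred-stimulus
indicator. `demo_run/` contains every table (outcomes, lick
probabilities, cell scores, decoding curves, activity summaries), a
`summary.json`, and a `manifest.json` with md5 hashes; rerunning with the
same config and seed reproduces the outputs bit for bit.

The same pieces are ordinary functions, e.g.

```r
v  <- task_variant("TPSD")
build_timeline(v, "P")$total_duration    # 1.4 (seconds)
build_timeline(v, "NP")$total_duration   # 4.2
dprime(0.84, 0.16)                       # 1.988916
lick_threshold(c(8, 12))                 # 7.171573
```

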