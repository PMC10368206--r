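Package: tpsd
Title: Behavioral and Population-Dynamics Analysis for Temporal Pattern
    Sensory Discrimination Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for go/no-go temporal pattern sensory
    discrimination (TPSD) experiments in head-fixed mice: trial schedules and
    stimulus timelines for rhythmic audiovisual patterns, discriminability
    (d-prime) learning curves with sliding best-window selection, lick-event
    probability profiles, time-binned bootstrapped support-vector-machine
    decoding of stimulus and trial outcome with shuffled-label controls and
    forward sequential feature selection, identification and removal of
    lick-modulated cells, bootstrap summaries of mean network activity,
    peak-activity-time distributions with Kolmogorov-Smirnov comparisons,
    and principal-component neural trajectories. A synthetic-data generator
    produces lick trains and deconvolved spike rasters with the statistical
    structure the analyses assume, so the full pipeline is testable without
    access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
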