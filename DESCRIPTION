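Package: p300tacs
Title: Phase-Locked tACS Oddball Pipeline: EEG Simulation, P300/ERO Analysis,
    and Crossover Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a within-subject crossover
    experiment in which transcranial alternating current stimulation (tACS) is
    phase-locked to the P300 event-related potential elicited by a visual
    oddball task. Provides a synthetic EEG and behavior generator with
    configurable ground truth, oddball sequence and tACS waveform scheduling
    with phase-locked target delays, on-site estimation of individual P300
    latency and event-related-oscillation frequency, offline ERP and Morlet
    time-frequency analysis with trial-by-trial artifact handling, visual
    oddball and d2 attention-test scoring, and the 2x2 repeated-measures
    statistics (partial eta squared, paired t with Cohen's d, change-score
    correlations with Holm correction) that tie the outcomes together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
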