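Package: somnotag
Title: Sleep Staging, Optotagging and Brain-State Transition Analysis for
    In Vivo Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for combined EEG/EMG, single-unit and behavioral
    recordings in rodent pain and sleep studies: rule-based classification of
    5-s epochs into wake, NREM and REM sleep from spectral band power and EMG
    amplitude; identification of opsin-expressing units by laser-evoked spike
    reliability, latency, jitter and waveform similarity, with spike-sorting
    quality metrics; brain-state-dependent firing rates, modulation indices
    and peri-event histograms; brain-state transition probabilities on 60-s
    bins with hierarchical (trials-within-mice) bootstrap confidence
    intervals and laser-effect tests; and mechanical/thermal nociception
    endpoints (50% paw-withdrawal threshold by the up-down method,
    paw-withdrawal latency). Includes a seeded synthetic-recording generator
    so every stage is testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
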