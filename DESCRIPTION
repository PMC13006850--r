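Package: somnocog
Title: Multi-Night Sleep EEG Microarchitecture and Next-Day Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multi-night, in-home sleep EEG studies
    of cognitive aging. Detects slow oscillations (amplitude/duration
    criteria on the 0.3-4 Hz band) and sleep spindles (sliding-window
    sigma-band features) on artifact-free N2/N3 sleep, computes per-night
    macro- and microarchitecture metrics (WASO, stage minutes, event
    densities), scores Go/NoGo and Simon switch task sessions, and links
    nightly sleep quality to next-day executive performance with
    generalized linear mixed models, intraclass correlation coefficients,
    parametric-bootstrap confidence intervals and power simulation. A
    synthetic-data generator (Markov-chain hypnograms, 1/f background EEG
    with injected ground-truth events, mixed-model behavioral outcomes)
    makes every stage verifiable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    tibble,
    glmmTMB,
    lme4,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    dplyr
Config/testthat/edition: 3
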