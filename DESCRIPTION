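Package: fipho
Title: Behavior-Coupled Fiber Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy workflow for dual-sensor fiber photometry recordings
    coupled to freely-moving behavior. Preprocesses demodulated photometry
    channels (zero-phase Butterworth low-pass, isosbestic least-squares
    regression, DF/F, Z-score), aligns Z-scored signals to retrospectively
    referenced behavioral events (onset-locked ensembles, before/during
    area-under-curve windows with normality-gated paired tests), maps
    signals onto board-normalized animal trajectories as occupancy-time
    normalized heatmaps, and generates fully synthetic sessions
    (photobleaching, shared motion artifacts, event-locked transients,
    biased-random-walk trajectories) for validation without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    readxl,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
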