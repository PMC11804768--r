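Package: coptools
Title: Posturography Signal Processing and Clinimetrics for Dual Force-Plate Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for posturography with a consumer corner-sensor balance
    board validated against a laboratory six-component force plate. Reads raw
    corner-force and force/moment wrench time series, builds per-sensor linear
    calibrations, filters and downsamples signals, aligns the two devices by
    cross-correlation, detects stable stance onset and selects analysis
    segments, computes center-of-pressure (COP) trajectories and the standard
    sway parameters (SD of displacement, mean velocity, pathlength, 95%
    prediction ellipse area), Welch power spectral densities, and the
    clinimetric statistics used for concurrent validity and test-retest
    reliability: the ICC family via ANOVA mean squares with F tests and
    confidence intervals, SEM, MDC, and absolute/relative device agreement.
    Includes a seeded synthetic-sway generator (Ornstein-Uhlenbeck model with
    device rendering) so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
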