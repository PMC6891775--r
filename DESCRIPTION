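Package: rdfd
Title: Altitude-Corrected Driving Fatigue Estimation from Heart Rate
    Variability and Blink Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates a driver's fatigue level from beat-to-beat heart
    period (R-R interval) recordings and spontaneous eye-blink events, for
    drives on mountain roads where rapid altitude change distorts heart-rate
    based measures.  Implements the variation coefficient of R-R intervals
    (RRVC = SDNN/M) as the windowed HRV feature, a normalized driving
    fatigue degree (DFD) statistic anchored to pre-drive baselines, a
    blink-frequency analogue of the same statistic, and an
    altitude-dependent cubic correction factor calibrated per slope
    direction that rescales the HRV-based DFD to the blink reference.
    Includes an R-peak detector for raw ECG traces, cubic trend fitting
    with inflection-point (fatigue breakpoint) detection, aggregation
    window selection by regression F statistics, curve agreement tests,
    and a synthetic physiological-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
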