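Package: pulsesync
Title: Heartbeat Detection, Validation and Cardiovisual Stimulation Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating heartbeat-synchronized visual
    stimulation pipelines of the kind used in cardiovisual full-body-illusion
    experiments. Simulates ground-truth beat trains and renders synthetic
    photoplethysmography (PPG, 134 Hz) and electrocardiography (ECG, 240 Hz)
    traces with configurable noise; detects pulse peaks causally with a bounded
    per-beat decision latency; scores detected beats against an ECG-derived
    reference via relative peak-to-peak interval RMSE and missed-beat counts;
    schedules synchronous and rate-shuffled asynchronous flash trains with a
    brightness envelope; and reproduces the study-analysis pipeline
    (questionnaire aggregation, bilateral pain deltas with instrument sign
    conventions, and normality-gated paired testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    nortest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
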