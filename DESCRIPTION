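Package: plastometrics
Title: Neuroplasticity Metrics for Neurofeedback-Guided Stroke Rehabilitation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies training-induced neuroplasticity in robot-assisted
    stroke rehabilitation from three complementary data streams. From EEG it
    computes mu-rhythm suppression scores used to trigger a robotic hand in
    closed loop, and a band-power linear-discriminant "discriminant rate"
    separating motor-imagery from rest over ipsilesional or contralesional
    electrode sets. From region-level resting-state BOLD time series it
    computes the temporal variability of dynamic functional connectivity in
    non-overlapping windows, averaged across window lengths and aggregated
    into functional subnetworks. Clinical outcomes (Fugl-Meyer upper-extremity
    scores at three time points) are analysed with tie-corrected rank
    statistics (Friedman, Wilcoxon signed-rank, Mann-Whitney,
    Scheirer-Ray-Hare) and a minimal-clinically-important-difference responder
    analysis. Seeded generators for synthetic EEG, state-switching BOLD, and
    clinical tables make every stage testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
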