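Package: pdwear
Title: Wearable Inertial Sensor Simulation and Symptom Detection for Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much wearable-sensor data is needed to
    train Parkinson's disease motor-symptom detectors. Simulates labelled
    cohorts of tri-axial accelerometer and gyroscope recordings with
    configurable tremor and bradykinesia effects, medication-state changes
    and sensor-replacement perturbations; segments recordings into
    five-second clips with zero-phase Butterworth filtering; extracts a
    56-dimensional time/frequency feature representation per sensor
    (including sample entropy and spectral moments); trains random-forest
    and one-dimensional convolutional network classifiers; and evaluates
    them with leave-one-subject-out AUROC across sensor combinations,
    activity groups, training-set sizes and recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
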