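Package: gaitdrift
Title: Heading Drift and Plantar Pressure Symmetry from Wearable Gait Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes inertial and plantar-pressure recordings of blindfolded
    straight-ahead walking into study-level estimates of heading bias. The
    pipeline synchronizes a body-worn IMU system with sensor shoe insoles via
    a leg-slap event, repairs missing samples with modified Akima
    interpolation, detects gait events (toe-off, mid-swing, heel strike) from
    sagittal-plane angular velocity, splits trials into walking segments at
    turns, estimates chest orientation by accelerometer-gyroscope fusion to
    obtain per-segment yaw slopes, computes stance-phase centre-of-pressure
    symmetry between the feet, and compares adaptation conditions with linear
    mixed-effects models and Tukey-adjusted pairwise contrasts. A synthetic
    trial generator with exact ground truth supports parameter-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    nlme,
    emmeans,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
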