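Package: cowmotion
Title: Detection of Active Mounting Behavior from Collar IMU Signals in Grazing Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an active-mount detector for
    free-grazing cattle from collar-mounted inertial measurement unit (IMU)
    recordings. Reads and writes a directory-of-CSV behavior event database,
    converts raw ADC counts to physical units, rotates body-frame
    accelerations into the world frame using the fused orientation
    quaternion, extracts a 112-dimensional time/frequency feature vector per
    7-second window, trains balanced one-vs-rest linear support vector
    machines under repeated stratified cross-validation, performs sequential
    backward feature selection and permutation importance, and statistically
    compares classifier performance between the body and world reference
    frames. Ships a synthetic five-behavior signal generator so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
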