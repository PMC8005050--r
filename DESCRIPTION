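Package: ethoacc
Title: Behavior Classification from Head-Mounted Triaxial Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify giraffe behavior from head-mounted triaxial
    accelerometer recordings. Supports two logger designs (a high-frequency
    burst-mode device and a continuous 1 Hz device), labeling of bursts from
    observed ethogram intervals, additive per-axis calibration across
    individuals using quiet-standing reference means, a per-burst feature set
    (per-axis moments, inverse coefficient of variation, spectral weighted
    mean frequency, and combined magnitude/pitch/roll), Random-Forest
    classification under leave-one-burst-out and leave-one-individual-out
    validation, and one-vs-rest accuracy/precision/recall reporting. Includes
    a seeded synthetic-data generator that emulates labeled behavior streams
    through both device models for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
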