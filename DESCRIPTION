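Package: adawin
Title: Adaptive-Window Segmentation and Classification of Animal Behavior
    from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for classifying livestock behavior (eating, lying,
    walking, standing) from body-mounted 10 Hz accelerometer/gyroscope
    streams. Implements stream validation via timestamps and counters,
    interquartile-fence outlier censoring with physical range limits,
    linear-interpolation gap filling, per-animal min-max normalization,
    fixed sliding-window and per-behavior adaptive-window segmentation,
    a 224-feature time/frequency registry plus accelerometer pitch and
    roll, five reference classifiers with stratified hold-out evaluation,
    window-size/step-size grid optimization, recursive feature
    elimination, and a labeled synthetic inertial-stream simulator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    caret,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
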