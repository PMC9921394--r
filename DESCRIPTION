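Package: exertrack
Title: Exercise Recognition and Repetition Counting from Wearable Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recognizes sequences of strength exercises (dips, pull-ups,
    squats separated by breaks) from streaming chest and hand accelerometer
    signals sampled at 30 Hz, and counts repetitions within each recognized
    activity segment. Activity recognition uses a compact one-layer 1-D
    convolutional network applied to sliding 50-sample windows with soft
    labels, followed by a post-processing block (moving-average smoothing,
    binarization, and run-length peak/gap elimination) that extracts labeled
    segments and the performed scenario. Repetition counting applies a
    zero-phase Butterworth low-pass filter to activity-specific informative
    channels and counts prominence- and distance-filtered peaks. A synthetic
    signal generator reproducing the protocol statistics of the underlying
    study makes the full pipeline trainable and testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
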