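Package: gaithht
Title: Gait Abnormality Detection from Pose Keypoints via Empirical Mode
    Decomposition and the Hilbert Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 2-D pose-estimation keypoint tracks (OpenPose-style JSON
    or flat CSV) into knee flexion/extension angle signals, decomposes the
    signals with a from-scratch empirical mode decomposition, computes the
    Hilbert amplitude/energy spectrum and a time-resolved energy trace,
    detects walking-to-turning transitions as prolonged low-energy segments,
    and classifies gait as normal, other-disorder, or Parkinson-like from
    IMF, energy and turn-duration features. Includes seeded synthetic gait
    and keypoint generators with known ground truth so every stage is
    testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    signal,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
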