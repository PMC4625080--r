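Package: emgcard
Title: Cardinality and Time-Domain EMG Features for Myoelectric Pattern
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and offline evaluation toolkit for
    myoelectric pattern recognition (MPR). Implements the cardinality
    feature (number of distinct quantized sample values in an analysis
    window) together with the classic Hudgins time-domain set and other
    comparative EMG features, sliding-window segmentation with contraction
    trimming, linear discriminant analysis and multi-layer perceptron
    classifiers, randomized 40/20/40 cross-validation with per-movement
    accuracy aggregation and Wilcoxon signed-rank comparisons, robustness
    sweeps over sampling rate, window length, contraction dynamics and ADC
    bit depth, and a synthetic multichannel EMG session generator so the
    whole pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
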