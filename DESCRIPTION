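Package: usvseverity
Title: Mouse Ultrasonic Vocalization Quantification and Multidimensional
    Behavioral Severity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mouse vocalizations recorded during courtship and
    distress testing and scores overall behavioral severity in a mouse model
    of Angelman syndrome. Provides a seeded synthetic-cohort generator
    (battery measures, call events with frequency contours, rendered
    two-channel audio), a spectrogram-based call detector with per-call
    contour extraction, call-level analyses (band taxonomies, inflection-based
    complexity, slope statistics, cross-microphone deduplication, spectral
    properties), per-mouse aggregation with unpaired t-tests and Fisher exact
    comparisons, and a standardize/PCA/k-means severity analysis reporting
    genotype-prediction accuracy and genotype-centroid distance in principal
    component space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
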