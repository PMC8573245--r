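Package: khknn
Title: Kernelized k-Local Hyperplane Nearest-Neighbor Classification and Clinical Stroke-Risk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance-based classification of small, imbalanced clinical
    cohorts with the k-local hyperplane distance nearest-neighbor model
    (HKNN) and its kernelized variant (KHKNN), in which each class is
    represented near a query by the affine hull of its k nearest neighbors
    and the query is assigned to the class with the smallest regularized,
    optionally kernel-space, hyperplane distance. Includes leave-one-out
    (jackknife) evaluation with a seven-metric confusion-matrix report
    (accuracy, sensitivity, specificity, precision, negative predictive
    value, F-score, Matthews correlation coefficient) with explicit NaN
    semantics, an MCC-driven (k, gamma) grid search, clinical risk-score
    calculators (CHADS2, CHA2DS2-VASc, GNRI, abdominal aortic calcification
    score), a synthetic-cohort generator for mixed binary/continuous
    features with per-feature target label correlations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
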