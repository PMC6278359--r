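Package: rivality
Title: Rivality and Modelability Indexes for QSAR Classification Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pre-modeling diagnosis and applicability-domain assessment of
    QSAR classification datasets from molecular descriptor tables. Computes
    the per-molecule rivality index (plain and neighborhood-weighted), the
    dataset modelability index (CMODI), activity-cliff and activity-border
    detection, cliff-erasure curation, an external-set applicability-domain
    protocol, and a Random Forest / linear-SVM benchmark harness for
    comparison against the distance-based diagnostics. Includes a synthetic
    descriptor-table generator with planted cliffs and borders so every
    analysis is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
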