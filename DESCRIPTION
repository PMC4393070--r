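Package: fuzzygrn
Title: Gene Regulatory Network Inference with Rule-Based Neuro-Fuzzy Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs signed, directed gene regulatory networks from short
    time-series expression data using per-gene rule-based neuro-fuzzy networks.
    Expression values are min-max normalized, fuzzified with three Gaussian
    membership functions (Low/Medium/High), and summarized as IF-THEN rules
    whose singleton consequent weights are learned by least squares.  Rules are
    canonicalized across the per-gene networks, thresholded into ternary
    effectivity symbols, and converted into activator/repressor edge evidence
    that is accumulated into a final signed network.  Includes KNN imputation
    for missing microarray values, precision/recall/F evaluation against a
    signed reference network, and a seeded synthetic-data simulator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
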