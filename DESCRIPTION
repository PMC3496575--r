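Package: twostageFDR
Title: False Discovery Rate Control for Two-Stage Screening Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis tests controlling the false discovery rate (FDR) in
    two-stage high-dimensional screening designs, where promising hypotheses
    are selected at an interim analysis and re-tested at the end of the second
    stage. Implements the three interim selection rules used in genomic
    screening (fixed p-value threshold, fixed-number selection, FDR-threshold
    selection with optional early stopping for futility), final tests based on
    second-stage data only ("pilot" approach) or on the pooled data of both
    stages via two-sided sequential p-values computed by numerical integration
    ("integrated" approach), and a Monte-Carlo simulation engine to estimate
    the realized FDR and power under independent, autoregressive, block- and
    equi-correlated test statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
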