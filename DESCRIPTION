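Package: constancer
Title: Constancy Assessment for Noninferiority Margins from Meta-Analytic Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-epidemiological assessment of the constancy
    assumption behind noninferiority margins. Harmonizes trial-level
    results from placebo-controlled trials to benefit-positive
    standardized mean differences, pools them by inverse-variance and
    DerSimonian-Laird random-effects models, splits each meta-analysis
    into its historical and most-recent components, quantifies time
    trends in placebo response, active response and effect size, and
    fits a sample-size-weighted stepwise regression that predicts a
    future trial's effect from the historical meta-analysis, yielding a
    discount factor for putative-placebo noninferiority margins. A
    synthetic-corpus generator with known ground truth supports
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
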