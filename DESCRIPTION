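Package: drsig
Title: Expression-Biomarker Discovery and Rule-Based Response Scoring for
    Drug-Sensitivity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for deriving expression biomarkers of drug response
    from cell-line panels: dose-response summarization (normalized area under
    the survival curve and IC50 with censoring), stratification into extreme
    responder and non-responder groups, a from-scratch two-class unpaired
    Significance Analysis of Microarrays with permutation-based false
    discovery control, hypergeometric pathway over-representation,
    Mann-Whitney and trend-based signature selection, and a gated
    Response-Average classifier with cross-platform quantile renormalization
    and confusion-matrix validation. Includes a synthetic-cohort generator
    with a planted signature so every stage can be checked against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
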