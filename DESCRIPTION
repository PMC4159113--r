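Package: preactivation
Title: Preactivated Oxidative-Stress Gene Analysis and Pathway Signature Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting oxidative-stress response genes that
    are "preactivated" in de-differentiated (EMT) cells and for scoring the derived
    pathway signatures in patient cohorts. Provides fold-change differential calling
    on log2 expression matrices, gene-set overlap and enrichment statistics with a
    numerically stable log-space hypergeometric upper tail, single-sample signature
    scores (sums of log expression), cohort stratification into high/low strata,
    Monte Carlo gene-set resampling nulls for signature-signature correlation,
    Kaplan-Meier and Mantel-Cox (log-rank) survival comparisons, responder-fraction
    summaries, and a synthetic-data generator with planted ground truth for
    end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
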