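Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining spontaneous adverse-event reporting databases in
    the FAERS quarterly ASCII dialect: ingestion and case-level deduplication,
    drug-name normalization to drug groups, assembly of per-case report records,
    drug-event 2x2 contingency tables, and four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio, the Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma-Poisson shrinker with an empirical-Bayes fitted prior), with the
    standard signal thresholds, strong-signal classification, MedDRA-level
    aggregation of signals to HLGT and SOC proportions, and demographic and
    outcome cohort summaries. Includes a synthetic report generator with
    planted signals of known strength so the whole pipeline is testable
    without access to the external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
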