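Package: ntsom
Title: Self-Organizing Map Anomaly Detection for Non-Target Screening
    Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric workflow for flagging anomalous wastewater
    samples from HPLC-HRMS non-target screening peak-area tables.
    Provides compound screening filters (blank ratio, dilution-response
    t-test, per-site dilution "Correctness" rule), two-way Ward
    hierarchical clustering for selecting compounds common to all sites,
    a deterministic batch Self-Organizing Map on a hexagonal lattice
    with Vesanto sizing heuristics and quality metrics (quantization
    error, topographic error, distribution matching error, dead nodes),
    quantization-error outlier flagging of projected samples, and a PCA
    score-distance/orthogonal-distance baseline classifier.  A synthetic
    feature-table generator emulates the urban/industrial study design
    (replicates, 1:10 dilutions, per-site blanks) so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
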