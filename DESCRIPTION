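Package: dialymet
Title: Plasma Metabolomics Pipeline for Hemodialysis Uremic Solute Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for capillary-electrophoresis
    mass-spectrometry plasma metabolomics of maintenance hemodialysis cohorts.
    Implements the standard data-reduction chain (80 percent missing-value
    rule, internal-standard normalization, pooled-QC relative-standard-
    deviation filtering, half-minimum imputation and unit-variance scaling),
    NIPALS principal component analysis with cross-validated predictive
    variance, linear SVM recursive feature elimination with repeated
    cross-validation stability selection, per-metabolite univariate testing
    (Mann-Whitney U, paired t) with Benjamini-Hochberg false-discovery-rate
    control, fold-change, metabolite-ratio and change-pattern region
    analyses, and a comparison of uremic-retention-solute clearance between
    low-flux and high-flux dialysis. A synthetic cohort generator with
    planted ground truth emulates the paired five-group study design so
    every stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
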