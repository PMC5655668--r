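Package: isopharm
Title: Isoform-Level Expression Biomarkers of Drug Response in Cancer Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Meta-analytical discovery and validation of transcript
    isoform-level expression biomarkers of in-vitro drug sensitivity in
    cancer cell line panels. Summarizes raw dose-response viability plates
    into the area above the curve (AAC) with Hill-curve fitting and
    sulforhodamine-B quality control, fits tissue-adjusted nested linear
    models at gene and isoform level, compares models by bootstrap
    out-of-bag concordance index with Wilcoxon signed-rank tests, combines
    coefficients and p-values across studies by sample-size weighting,
    calls biomarkers under joint FDR and concordance-index thresholds, and
    applies sign-consistent validation rules in independent datasets. A
    fully synthetic multi-study data generator with planted effects makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
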