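Package: txconcord
Title: Cross-Model Transcriptomic Concordance and Single-Cell DEG Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcriptomic dysregulation across disease
    models (e.g. human cortical organoids versus mouse cortex): replicated
    differentially-expressed-gene (DEG) calling with a low-power fallback
    rule, quadrant overlap enrichment against a defined background universe
    (geometric mean enrichment with a one-sided Fisher exact test),
    threshold-swept log fold-change regression, sign-consistency analysis of
    discordant genes, single-cell QC and normalization, a rank-based
    differential-expression engine, cluster-downsampled DEG-burden and
    cell-type composition procedures, and synthetic data generators with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
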