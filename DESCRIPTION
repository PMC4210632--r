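Package: salmocross
Title: Transcriptome Comparison of Wild, Hybrid and Domesticated Salmon Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, re-usable pipeline for two-colour (common-reference)
    microarray comparisons of wild, hybrid (domesticated dam x wild sire) and
    domesticated Atlantic salmon fry at two life stages. Covers probe-level
    quality filtering and intensity-dependent (lowess) normalisation, Welch
    t-test and Welch ANOVA differential expression with Benjamini-Hochberg
    FDR, a directional gene-set perturbation test in the GAGE style,
    redundancy grouping of significant pathways and extraction of strongly
    responding member genes, and classification of expression inheritance
    modes in hybrids (additive, maternal/domesticated dominant, paternal/wild
    dominant, overdominant) from the additivity parameter alpha and the
    dominance deviation delta. A synthetic-data generator emulates the
    3-cross x 2-stage x 6-replicate design with planted ground truth so that
    every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
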