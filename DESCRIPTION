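Package: crossmark
Title: Cross-Platform Consensus Marker Discovery and Subtype-Aware Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovers cell-population-specific marker transcripts by merging
    fold-change ranks and false-discovery-rate calls across four independent
    differential-expression analysis channels (two count-based, two
    intensity-based), and evaluates a candidate marker's prognostic value in
    tumor cohorts: molecular-subtype assignment by k-nearest-neighbor matching
    of signature genes, Kaplan-Meier curves and log-rank tests on
    median-dichotomized expression, and univariate plus subtype-adjusted Cox
    proportional-hazards models with Efron tie handling. Includes seeded
    synthetic-data generators with known ground truth for every pipeline
    stage, auxiliary group statistics (delta-delta-CT fold change, Welch t,
    Kruskal-Wallis with Dunn post-hoc, Grubbs outlier exclusion), and
    readers for tab-separated expression/clinical tables and GEO
    series-matrix files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
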