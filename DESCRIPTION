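Package: aneumatch
Title: Multidimensional Matched-Cohort Construction and Outcome Comparison
    for Intracranial Aneurysm Surgery Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds matched surgical cohorts for intracranial aneurysm studies
    by k-nearest-neighbour case-based reasoning under a Z-score-standardized,
    weighted Euclidean dissimilarity, stratified by rupture status and by the
    frontal base-dome-angle quadrant, with sequential one-to-one assignment
    and deterministic conflict adjudication. Ships the downstream comparison
    engine (expected-cell-count routing between chi-square and Fisher's exact
    test; Lilliefors/Levene routing between the t-test and the Mann-Whitney U
    test), baseline-balance and outcome tables, morphometric derivations
    (size ratio, aspect ratio, dome-angle categories), and a seeded synthetic
    cohort generator with planted matched twins for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
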