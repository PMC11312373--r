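Package: inflascore
Title: Systemic Inflammation Scoring and Age-Related Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the INFLA-Score, a composite index of low-grade
    systemic inflammation built from decile points for C-reactive protein,
    white blood cell count, platelet count and the neutrophil-to-lymphocyte
    ratio, and analyses its association with age-related hospitalization,
    premature death (death before age 75) and life expectancy in
    prospective cohort data. Includes Cox proportional-hazards and
    restricted cubic spline dose-response models with subgroup and
    sensitivity runners, dietary pattern scoring (HEI-2020, Mediterranean,
    DASH and a 6-point healthy-diet covariate), joint diet-by-inflammation
    cross-classification, life-table attribution of expectancy differences
    to exposure groups, and a seed-reproducible synthetic cohort generator
    emulating the statistical structure of a UK-Biobank-like population.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    splines,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
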