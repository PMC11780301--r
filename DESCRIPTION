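Package: digigap
Title: Digital Divide and Individual-Level Health Inequality in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study whether internet access and internet use are
    associated with individual-level health inequality among older adults.
    Provides scoring of common health instruments (self-rated health, 6-item
    ADL and iADL scales, a 0-30 cognitive screen), the Kakwani relative
    deprivation index of health (whose sample mean equals the Gini
    coefficient), digital access and use indicators, covariate-adjusted
    linear models with fully standardized coefficients, moderation and
    subgroup analyses, and a propensity-score-matching sensitivity analysis
    with nearest-neighbor 1:1 matching, paired ATT tests and standardized
    mean difference balance diagnostics. A synthetic cohort generator with
    known confounding and treatment-effect structure makes the full pipeline
    testable without restricted survey microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
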