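Package: brainbody
Title: Brain-Body Vulnerability Analysis with Regional Vulnerability Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-subject Regional Vulnerability Indices (RVIs) from
    regional cortical thickness tables against disorder-specific expected
    patterns, with rank-based inverse normal transformation of
    covariate-adjusted residuals. Provides normality-gated two-group
    inference with false-discovery-rate adjustment and analytic post-hoc
    power, Kaiser-Meyer-Olkin adequacy screening with Horn's parallel
    analysis and varimax-rotated principal components over combined
    brain and physical-health batteries, anthropometric and fitness
    derivations (Durnin-Womersley/Siri body composition, Chester step-test
    VO2max), and a seeded synthetic-cohort generator so the full pipeline
    is testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
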