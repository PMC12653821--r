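Package: cogagedelta
Title: Cognitive Age Delta Estimation and Biomarker-Stratified Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a cognitive age for each participant in a
    neuropsychological cohort from age-sensitive test scores, corrects the
    regression-to-the-mean bias of age prediction models, and derives the
    Cognitive Age Delta (CAD), the difference between bias-corrected
    predicted cognitive age and chronological age. Participants are
    stratified by cerebrospinal-fluid amyloid/tau status within the AT(N)
    framework and by MRI-derived cerebrovascular burden (Fazekas score,
    cerebral microbleed count), and CAD is related to demographic, genetic,
    lifestyle and cognitive-reserve factors through grouped general linear
    models with false-discovery-rate control. A synthetic-cohort generator
    with planted effects makes every stage of the pipeline testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
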