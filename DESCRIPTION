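Package: gxlife
Title: Gene-Lifestyle Interaction Analysis for Obesity and Its Morbidities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how a polygenic score for
    body-mass index interacts with a composite obesogenic lifestyle score.
    Provides a synthetic cohort simulator (logistic liability for prevalent
    obesity, proportional-hazards incident endpoints with BMI-mediated
    genetic effects), lifestyle factor classification and weighted scoring,
    polygenic-score standardization and quintile stratification, exclusion
    accounting, Cox and logistic effect estimation including a 3x3 joint
    genetic-by-lifestyle grid and isolated effects, absolute risk-by-age
    prediction from the Breslow baseline, additive (RERI) and multiplicative
    interaction with attributable-proportion decomposition and bootstrap
    confidence intervals, and a morbidity association scan with
    BMI-mediation assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
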