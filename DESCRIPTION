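Package: pmutual
Title: Dynamic Mutualism Analyses for the General Psychopathology Factor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing dynamic mutualism against common-cause accounts
    of the general psychopathology (p) factor in longitudinal symptom panels.
    Provides a normal-theory covariance-structure engine (maximum likelihood and
    full-information maximum likelihood estimation, fit indices, Wald,
    likelihood-ratio and chi-bar-square boundary tests, measurement-invariance
    ladders), longitudinal bifactor models with the full bifactor strength and
    reliability index set (ECV, omega family, relative omega, H), the
    random-intercept cross-lagged panel model comparison family, Gaussian
    graphical network estimation with EBIC model selection, centrality,
    small-worldness, bootstrap stability and permutation network comparison
    tests, plus a seeded synthetic panel generator emulating common-cause,
    mutualism and differentiation data-generating processes with monotone
    attrition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
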