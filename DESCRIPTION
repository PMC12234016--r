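Package: twinstab
Title: Longitudinal Twin Models of Trait Stability and Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classical twin analyses of repeatedly measured
    phenotypes: a two-group (MZ/DZ) structured-covariance maximum-likelihood
    engine with full-information handling of missing data, univariate
    ACE/ADE/AE variance decompositions, multivariate Cholesky decompositions,
    common pathway (latent stability) models and correlated-factor models,
    together with the phenotypic stage (transforms, longitudinal and
    cross-twin correlations, internal consistency, exploratory and
    confirmatory factor analysis of item-level data). Includes a synthetic
    twin-data generator with known biometric structure so that every model
    can be validated end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
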