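Package: altsr
Title: Cross-Lagged Dynamics Between DNA Methylation and Cardiometabolic
    Traits in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Longitudinal epigenetic analysis of cardiovascular disease in
    twin cohorts: per-CpG linear mixed-model epigenome-wide association
    scans with person-nested-in-pair random effects, bivariate
    autoregressive latent trajectory models with structured residuals
    (ALT-SR) for cross-lagged effects between CpG methylation and
    cardiometabolic traits, and latent growth curve mediation from
    methylation through traits to disease. Includes a full-information
    maximum likelihood structural equation engine with equality
    constraints, fit indices and cluster-robust standard errors, and a
    twin-cohort simulator with a known bivariate ALT-SR data-generating
    process for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
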