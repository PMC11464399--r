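Package: lifecourse
Title: Bayesian Relevant Life-Course Exposure Modelling for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative contribution of an exposure measured across
    childhood, adolescence and young adulthood to a later-life health outcome.
    Implements the Bayesian relevant life-course exposure model: a regression of
    the outcome on a total lifetime effect multiplied by a Dirichlet-distributed
    simplex of life-stage weights, with a Poisson-likelihood log-link
    parameterization for relative risks on binary outcomes and a Gaussian
    likelihood for continuous outcomes. Supporting machinery covers individual
    growth-curve interpolation of missing exposure measurements (linear mixed
    models via lme4), age- and sex-specific z-score standardization, life-stage
    averaging, area-under-curve covariate summaries, multiple imputation of
    covariates by predictive mean matching with draw-pooling across imputations,
    classification of fitted weight vectors against accumulation and critical
    life-course hypotheses by Euclidean distance, and a synthetic-cohort
    generator emulating a prospective cardiovascular cohort design so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
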