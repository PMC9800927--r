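Package: gpdom
Title: Additive-Dominant Genomic Prediction for Clonally Propagated Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage genomic prediction pipeline for heterozygous clonal
    panels evaluated in unbalanced multi-environment trials. Stage one fits a
    trial mixed model per trait and returns clone BLUPs, prediction error
    variances and deregressed BLUPs. Stage two builds additive (VanRaden) and
    dominance (classical and genotypic parameterizations) genomic relationship
    matrices and a Gaussian kernel, and predicts breeding and genotypic values
    by G-BLUP (average-information REML), RKHS kernel regression, and Bayes B /
    Bayes C-pi Gibbs samplers. Includes seeded k-fold cross-validation with
    predictive ability and dispersion bias, mixed-model method comparison with
    Tukey letters, selection-differential and breeding-cycle efficiency
    analytics, Cohen's kappa selection coincidence, and a synthetic-data
    generator emulating a cassava germplasm panel with controlled
    additive/dominance variance partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    coda,
    multcomp,
    jsonlite,
    rlang,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
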