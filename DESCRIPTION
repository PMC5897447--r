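Package: serogp
Type: Package
Title: Additive Gaussian Process Modelling of Longitudinal Serum Proteome Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising sources of variation in longitudinal
    label-free proteomics studies of early childhood. Protein quantification
    tables in the MaxQuant proteinGroups dialect are filtered (decoy and
    modification-site-only hits, unique-peptide and run-coverage thresholds),
    technical replicates are collapsed to sample medians, and log2 expression
    matrices with explicit missingness are derived without imputation. Each
    protein's trajectory is modelled with an additive Gaussian process whose
    kernel components represent age (squared exponential), sampling season
    (periodic), gender and living environment (categorical), individual
    variation (categorical subject kernel) and an age-by-individual
    interaction. Covariate effects are selected across the 16 candidate
    covariate combinations by cross-validated mean log predictive density:
    closed-form leave-one-out for time-varying covariates and leave-subject-out
    stratified cross validation for subject-constant covariates. Cord-blood and
    follow-up proteomes are compared on ranked intensities with a paired rank
    product test (permutation percentage of false prediction) and per-subject
    Spearman correlations with Benjamini-Hochberg control. A synthetic-data
    generator reproduces the longitudinal study design with known ground truth
    so that power and type-I behaviour of the whole pipeline can be audited.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
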