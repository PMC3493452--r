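Package: ltassoc
Title: Informed Conditioning on Clinical Covariates in Case-Control
    Association Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association testing under the liability threshold
    model with covariate effects informed by external epidemiological data.
    Fits liability-scale covariate coefficients and the affine (prevalence)
    term from published prevalence-versus-covariate curves by an analytic
    probit-scale least-squares solve, computes per-sample posterior mean
    residual liabilities (truncated-normal tail expectations, with an exact
    mode for covariates measured at disease onset), and tests SNP
    association with a generalized Armitage trend test of genotype against
    the posterior means, optionally residualizing on nuisance covariates
    such as principal components. Includes the standard comparison
    statistics (logistic regression with and without covariates, joint
    gene-by-covariate tests, subset and case-only tests), a vectorized
    simulation engine for stratified case-control-covariate designs with
    liability or logit generative models, and closed-form noncentral
    chi-square power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    BiocGenerics,
    GenomeInfoDb,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GenomeWideAssociationStudies, StatisticalMethod, SNP, Genetics
RoxygenNote: 7.3.3
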