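Package: proxygwas
Title: Proxy-Phenotype Imputation Boosted GWAS with Replication and
    Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association studies of imputed
    phenotypes. Costly target phenotypes (such as DXA body-composition
    measures) are predicted from cheap proxy phenotypes via
    sex-stratified linear models trained in a small measured subset, and
    the imputed values are analysed at full-cohort scale. The package
    provides a seed-deterministic synthetic cohort simulator with a known
    latent adiposity factor, phenotype preprocessing (log transform,
    outlier trimming, covariate residualisation, inverse rank-normal
    transform), fast per-variant additive association, spectral
    estimation of the effective number of independent traits,
    distance-based clustering of significant signals into
    quasi-independent loci with novelty filtering and proximity gene
    annotation, replication power calculations with one-sided FDR and
    sign tests, and Bayesian colocalisation (approximate Bayes factors)
    together with SMR and HEIDI statistics for causal-gene
    prioritisation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
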