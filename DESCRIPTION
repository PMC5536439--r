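Package: admixscan
Title: Admixture Mapping with Gene-Environment Interaction for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for admixture-mapping gene-environment analyses in two-way
    admixed (African-European) case-control cohorts. Provides a synthetic-cohort
    simulator with known local-ancestry tracts, array-style genotype and sample
    quality control, ancestry-informative-marker selection, diploid local-ancestry
    inference by a hidden Markov model with global ancestry and principal
    components, per-marker logistic models with local-ancestry-by-BMI interaction
    (continuous, trend, per-SD and stratified parameterizations, conditional
    adjustment, and a multi-degree-of-freedom likelihood-ratio interaction test),
    inverse-variance fixed-effects meta-analysis with heterogeneity statistics,
    and empirical genome-wide significance by paired min-p permutation alongside
    effective-number-of-tests (simpleM) thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
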