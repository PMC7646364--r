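Package: parimpute
Title: Virtual Parental Genotypes from Sibling and Half-Sibling Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates indirect parental genetic effects on offspring
    phenotypes when parents are not genotyped. Imputes expected ("virtual")
    parental genotype dosages from sibling and half-sibling pair genotypes by
    Bayesian conditioning under Hardy-Weinberg equilibrium and Mendelian
    transmission, for autosomal and non-pseudoautosomal X loci. Provides an
    exact enumeration engine for the joint family genotype distribution,
    closed-form expected covariance structure of phenotypes and (imputed)
    dosages under additive trait models, non-centrality-parameter based
    asymptotic power and sample-size calculations for omnibus and conditional
    likelihood-ratio tests, a family simulator with genotype-dependent
    parental missingness, full-information maximum-likelihood linear mixed
    models with a family random intercept, genome-wide association scans, and
    unweighted polygenic-score analyses. Reads and writes PLINK binary
    (.bed/.bim/.fam) genotype files and a plain-text parental dosage format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
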