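Package: polyscreen
Title: Allele-Count Polygenic Scores from a Testosterone-SNP Screening Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-stage screen of GWAS-derived
    testosterone-increasing alleles against muscle-related traits
    (sex-concordance filter, covariate-adjusted per-variant association,
    autosome restriction, multi-trait summary-statistic lookup), an
    unweighted allele-count polygenic score with carrier dichotomization,
    the exact Poisson-binomial score distribution implied by
    Hardy-Weinberg equilibrium, and case-control validation statistics
    (odds ratio, chi-square, covariate-adjusted correlation, Wilks
    strength normalization). A synthetic-cohort generator produces
    genotype and phenotype data with the statistical structure the
    analysis assumes, so every stage runs and verifies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
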