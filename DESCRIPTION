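Package: hucgrs
Title: Candidate-Gene Association and Genetic Risk Scores for Heroin
    Craving Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene quantitative-trait
    association with heroin-use and craving (HUC) questionnaire phenotypes.
    Scores the 14-item HUC instrument into urge, ability and total craving
    phenotypes, quality-controls SNP genotype tables (Hardy-Weinberg
    equilibrium, minor allele frequency, call rate, duplicate concordance),
    fits covariate-adjusted single-SNP linear models under additive,
    dominant and recessive genotype codings, derives per-SNP risk-allele
    codings from genotype-stratified phenotype means, builds an unweighted
    genetic risk score and tests its dose-response trend.  Includes a
    synthetic genotype-phenotype cohort generator with known truth for
    power, calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
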