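Package: respomics
Title: Multiomics Prediction of Antipsychotic Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying antipsychotic treatment
    response in schizophrenia from genotype and DNA methylation data: PANSS
    reduction-rate outcomes and responder labels, polygenic and polymethylation
    risk scoring (LD clumping, p-value thresholding, permutation empirical P,
    two-stage pathway stacking), epigenetic clock measures, differential
    methylation and region detection, cis-meQTL scanning, Bayesian
    colocalization, SMR/HEIDI summary-based Mendelian randomization,
    proxy methylation imputation from meQTL genotypes, and combination-pattern
    response models evaluated by AUC, regression error metrics and decision
    curve analysis. Ships a seeded synthetic cohort generator with planted
    genetic and epigenetic effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    vcfR,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
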