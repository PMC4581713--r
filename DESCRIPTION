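Package: brcarisk
Title: Breast Cancer Absolute Risk Prediction with Mammographic Density
    and Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for 10-year absolute breast
    cancer risk prediction in a screening cohort. Generates synthetic screening
    cohorts with the covariate structure of a Singapore mammography screening
    programme, simulates case-status-conditional genotypes for a 75-SNP panel
    and the derived genetic risk score, fits nested Cox proportional-hazards
    models (Gail variables + BMI, adding mammographic dense area, adding the
    genetic risk score), converts fits to individual 10-year absolute risks via
    a Nelson-Aalen cumulative baseline hazard, and evaluates discrimination
    (cross-validated AUC averaged over genotype replicates, Gonen-Heller
    concordance probability) and predictive values at fixed risk thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
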