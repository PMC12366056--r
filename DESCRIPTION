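Package: cadtrans
Title: Trans-Omics Subtyping and Machine-Learning Prediction of Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating a targeted plasma metabolomics panel with
    genome-wide SNP genotypes to derive genetic-metabolic subtypes of coronary
    artery disease (CAD) and to train consensus machine-learning risk models.
    Implements median/log2 and unit-variance metabolite normalization, SNP
    quality control (minor allele frequency, Hardy-Weinberg equilibrium in
    controls, missing rate) with {0, 0.5, 1} genotype encoding and median
    imputation, K-means clustering of each omics layer with elbow-based model
    selection and Jaccard cluster-stability comparison, allelic case-control
    association with Bonferroni control, rule-based five-SNP haplotype calling,
    cluster cross-tabulation enrichment and subtype assignment, orthogonal
    partial least squares discriminant analysis (OPLS-DA) with k-fold Q2 and
    the Hotelling T2 95% ellipse, bootstrapped LASSO/random-forest/SVM
    consensus feature selection, model evaluation (AUC, AUC-PR, Brier score,
    calibration), and a seeded synthetic-cohort generator that emulates the
    cohort structure the analysis assumes so the full pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
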