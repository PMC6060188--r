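Package: flucipet
Title: Semiquantitative Analysis of Dynamic Fluciclovine Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semiquantitative analysis of dynamic amino-acid
    (fluciclovine) brain PET in glioma. Generates seedable 4D dynamic
    phantoms in SUV units with ground truth, builds spherical and
    contralateral-mirror regions of interest, segments metabolically
    active tumor at multiples of the contralateral background SUVmean,
    extracts SUVmax/SUVmean and tumor-to-background (TBmax, TBmean)
    metrics per time frame, assesses time-activity-curve equilibrium
    with unbalanced two-way ANOVA and Tukey post hoc tests, derives ROC
    cutoffs discriminating high- from low-grade glioma, screens
    predictors with lasso-regularized logistic regression, and
    correlates uptake with the Ki-67 proliferation index. Includes a
    reproducible end-to-end pipeline and NIfTI/TSV/CSV/JSON readers and
    writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    glmnet,
    car,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
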