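Package: gliorad
Title: Radiomic Grading of Malignant Gliomas from Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A radiomics pipeline for binary grading of malignant gliomas
    (WHO grade III versus IV) from co-registered contrast-enhanced
    T1-weighted and T2-weighted MR volumes with tumor masks. Implements
    whole-brain Z-score normalization, isotropic resampling with
    shape-based mask interpolation, an undecimated 3D Coiflet wavelet
    filter bank, IBSI-style shape, intensity, histogram and gray-level
    texture features (GLCM, GLRLM, GLSZM, NGLDM, NGTDM) over multiple
    quantization levels, Wilcoxon-Mann-Whitney screening followed by
    L1-regularized logistic regression feature selection with repeated
    cross-validated penalty tuning, and five classifier families
    evaluated by leave-one-out cross-validation and independent
    validation. A seeded synthetic phantom generator provides two-class
    cohorts so the whole analysis runs and is tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    nnet,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
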