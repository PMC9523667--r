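Package: nodiomics
Title: Radiomic Classification of Mesorectal Lymph Nodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics workflow for discriminating benign from
    malignant mesorectal lymph nodes on high-resolution T2-weighted MR slices.
    Provides a synthetic lymph-node phantom generator with configurable size
    distributions, border morphologies and internal signal heterogeneity; four
    ROI-derivation geometries (node contour, contour expanded by 2-3 mm,
    annular rim, inscribed circle); a 1,409-feature radiomic bank (shape,
    first-order, five texture-matrix families, and a 14-transform filter
    bank); ICC-based feature stability screening against simulated
    re-segmentation; a variance/SelectKBest/Lasso selection cascade; and
    logistic modelling with stratified cross-validation, ROC metrics, Youden
    cutoffs and DeLong AUC comparison, including benchmarks against binary
    human raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
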