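Package: glandmetrics
Title: Gland Histomorphometry and Biochemical Recurrence Modeling for
    Prostate Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-driven tile extraction from prostate whole-slide
    images, stain-deconvolution segmentation of lumen, epithelium and
    stroma, per-gland histomorphometric features (roundness, area, wall
    thickness, cell fraction), tumor-volume estimation from prostate
    voxel masks, and the statistical battery used to relate pathomic
    features to biochemical recurrence (t-tests, logistic models with
    ROC/AUC and DeLong intervals, permutation AUC comparison,
    Benjamini-Hochberg correction, Kaplan-Meier/log-rank and Cox
    proportional hazards, risk stratification). Includes a synthetic
    H&E slide and cohort generator with analytically known ground truth
    so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    survival,
    jsonlite,
    png,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Pathology, Survival
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'histomorphometry.R'
    'io.R'
    'stain.R'
    'tiling.R'
    'synthetic-cohort.R'
    'synthetic-slide.R'
    'pipeline.R'
    'recurrence.R'
    'tumor-volume.R'
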