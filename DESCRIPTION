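Package: thoraseg
Title: Automated Thoracic Cavity Segmentation and Tumor Burden
    Quantification for Mouse Lung MicroCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated segmentation of mouse thoracic microCT
    volumes for longitudinal lung tumor burden readouts. Builds a
    thoracic cavity mask from the ribcage (bone thresholding, largest
    3D connected component, slice stacking, clockwise-ordered innermost
    rib points joined by a periodic spline, with a two-pass refinement),
    classifies in-cavity voxel densities into lung, intermediate and
    soft tissue with a one-dimensional k-means (k++ seeding), trims the
    volume at the tracheal bifurcation and the diaphragm (per-column
    intensity inflection), and reports tissue percentages of the
    thoracic cavity and volumes in cubic millimetres. Includes a
    synthetic thorax phantom generator with exact ground-truth labels,
    NIfTI-1 and multipage TIFF input/output, and validation utilities
    (Dice coefficient, Spearman rank correlation, Bonferroni-corrected
    group comparisons, longitudinal summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
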