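Package: vertmorph
Title: Automated Vertebral Body Morphometry from CT Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts anterior, posterior and central vertebral body heights
    from labeled spine segmentation masks using a landmark algorithm
    (midsagittal slice selection, posterior-element removal, four-vertex
    polygon approximation of the body contour, Bresenham-corrected central
    endplate landmarks), and provides the cohort-level statistical machinery
    built on such heights: sex-stratified height and index tables, pooled
    t-tests and power analysis, ICC(2,k) reader agreement, cubic
    truncated-power spline mixed-effects regression with knots at T9/L1,
    and intra-individual vertebral height-ratio (Pseudo-Jacobian) matrices.
    Includes a synthetic-data module generating masks with exact landmark
    ground truth and height cohorts with known generative parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    lme4,
    RNifti,
    jsonlite,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
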