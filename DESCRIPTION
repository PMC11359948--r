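Package: retquant
Title: Quantitative Retinal Biomarkers from OCT and OCTA Projection Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts a canonical 452-dimensional biomarker vector per eye from
    en-face OCT/OCTA projection images and vessel/FAZ segmentation masks:
    59-bin uniform local binary pattern (LBP) texture histograms for three
    projection slabs in both modalities, windowed vessel morphology indices
    (area density, skeleton density, perimeter index, diameter index,
    complexity index, branch-point complexity, curvature shape parameter)
    with distribution summaries and box-counting fractal dimension for
    capillary and large-vessel masks, and twelve foveal avascular zone (FAZ)
    morphometric parameters. Provides univariate feature selection with a
    Shapiro-Wilk normality gate, nested cross-validated classification of
    disease status with importance-threshold pruning, biomarker importance
    ranking with per-feature-type contribution percentages, and fully
    seeded synthetic cohort generators so the whole pipeline is testable
    without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    pracma,
    e1071,
    randomForest,
    ranger,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
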