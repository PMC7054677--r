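Package: amyquant
Title: Quantification of Amyloid Plaques and Plaque-Associated Microglia in Fluorescence Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying amyloid-beta plaque burden and
    plaque-associated microglia in multichannel fluorescence micrographs of mouse
    brain sections. Segments nuclei (Gaussian blur, Otsu thresholding, watershed on
    the Euclidean distance map) and plaques (blur, Otsu, area filter); measures
    per-cell marker expression, Iba1 positivity, distances to the nearest plaque
    border and radial intensity profiles; implements a fixed-threshold area-ratio
    workflow with leave-one-out 2-SD image quality control; provides design-based
    stereological estimators (Cavalieri point counting, optical-fractionator-style
    density); pools image-level metrics by per-animal medians into group mean and
    SEM; and ships the group-comparison statistics layer (unpaired t-test, per-bin
    Bonferroni, Pearson correlation, one-way ANOVA with Tukey HSD, iterative Grubbs
    outlier removal). A seeded synthetic-cohort generator with full ground truth
    makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
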