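Package: FibroSeg
Title: Semi-Automated Quantification of Myocardial Fibrosis in H&E Histology
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Seeded segmentation and quantification of collagenous (fibrotic)
    tissue in hematoxylin-and-eosin stained myocardial images. Provides a
    CIELAB color segmenter (per-pixel Delta-E distance to the mean color of a
    pathologist-drawn seed region, thresholded at a configurable tolerance), a
    Gabor filter-bank texture segmenter (oriented multi-scale filter energies,
    Gaussian smoothing, joint color-texture features, k-means with k = 2), a
    ground-truthed synthetic tile generator for validating both segmenters,
    and an evaluation layer that scores per-image fibrosis percentages against
    manual annotation with a ten-percentage-point correctness rule, combines
    methods by a union rule, and reproduces aggregate accuracy tables from a
    packaged per-image study dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
biocViews: Software, CellBiology, Classification, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
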