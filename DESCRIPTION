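Package: NeutroTrack
Title: Quantification of Chemokine Receptor Internalization and Neutrophil
    Migration at Wounds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of neutrophil behaviour at
    wound sites in time-lapse fluorescence microscopy. Scores chemokine
    receptor internalization per cell as gray-level co-occurrence contrast
    over seeded active-contour (Chan-Vese) or threshold segmentations, with
    reference-region and per-movie normalizations and spatial gradient
    profiling against a wound margin. Classifies cell trajectories into
    forward and reverse segments relative to the occupied wound area (owa)
    polygon and computes speed, approach-angle, straightness, net reverse
    traffic, recruitment and cluster-size statistics. Includes a synthetic
    scene and biased persistent random walk generator with ground-truth
    labels so every analysis stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation, CellBasedAssays
RoxygenNote: 7.3.3
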