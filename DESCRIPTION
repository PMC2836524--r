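Package: cariesFD
Title: Occlusal Caries Screening from Intraoral Images via Fractal
    Dimension and Discoloration Area
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments pit-and-fissure discoloration from intraoral tooth
    photographs, quantifies lesion morphology by the box-counting fractal
    dimension (FD) and the proportion of discolored area on the occlusal
    surface (PA), and classifies teeth into preventive versus operative
    treatment with two-class linear discriminant functions, including
    built-in reference formulas and their decision thresholds.  A
    Minkowski (dilation) estimator provides an independent cross-check of
    the box-counting dimension.  Diagnostic performance metrics
    (sensitivity, specificity, accuracy), Spearman rank correlation, and
    synthetic tooth-image and feature-table generators allow the whole
    pipeline to be validated end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
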