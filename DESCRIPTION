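Package: scarkit
Title: Quantitative Analysis of Incisional Scar Healing in Rodent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of incisional wound healing in
    rodent studies: collagen fiber organization analysis of Masson's-trichrome
    histology (blue-red ratio segmentation, weighted vector summation
    orientation fields, axial directional variance, fiber density and blue
    intensity over standard scar/flank regions), wound histomorphometry with
    contraction, severity, healing and remodeling indices, calibrated scar
    planimetry from photograph annotations, visual-analog-scale histology score
    aggregation, and the normality-gated group-pooling statistical pipeline used
    to compare treatment arms. Includes seeded synthetic-data generators (fiber
    phantoms with von Mises orientation ground truth, morphometry tables, scar
    time-series, rater scores) so the full pipeline is testable end-to-end
    without access to the original slides and photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
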