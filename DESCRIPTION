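Package: synspread
Title: Quantification of Alpha-Synuclein Pathology Spread in
    Compartmentalised Microfluidic Neuron Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis and statistical workflow for two-chamber
    microfluidic neuron cultures seeded with alpha-synuclein preformed
    fibrils. Segments phosphorylated alpha-synuclein (pSer-129) pathology
    by channel thresholding, neurite (beta-III-tubulin) colocalisation,
    connected-component extraction and a minimum-area filter; normalises
    per-field metrics to 0.25 mm^2, aggregates chambers by Grubbs-filtered
    medians, and fits time-course regressions and non-parametric group
    comparisons. Classifies reverse-chamber pathology as transported versus
    transferred via a CFSE overlay, and measures fibril-puncta transport
    speed and direction from microchannel kymographs. A ground-truthed
    synthetic-microscopy generator emulates every assay so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
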