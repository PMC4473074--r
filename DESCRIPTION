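Package: gangliomsi
Title: MALDI Imaging Mass Spectrometry Quantification of A-Series Gangliosides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Adduct-resolved quantification of A-series gangliosides (GM3,
    GM2, GM1, GD1a) in MALDI imaging mass spectrometry of lesioned rodent
    brain. Computes theoretical monoisotopic masses and negative-mode adduct
    m/z values from compositional building blocks, reads and writes imzML
    spectral images, averages spectra over polygonal regions of interest,
    subtracts a moving low-percentile baseline, integrates peak areas, and
    quantifies each ion as the ratio of the ipsilateral (lesioned) to the
    mirrored contralateral region. Group-level inference uses one-way ANOVA
    with Tukey post-hoc comparisons. A synthetic spectral-image generator
    with known ground truth drives testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    xml2,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
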