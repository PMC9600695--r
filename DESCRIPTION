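Package: colonyscreen
Title: Quantitative Screening of Colony Biofilm Wrinkling, Growth, and
    Sporulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and plate-reader machinery for high-throughput
    phenotypic screens of Bacillus subtilis colony arrays. Quantifies biofilm
    colony wrinkling from plate photographs (morphological background
    subtraction, binarization, component filtering, radial wrinkling
    intensity normalized to colony area, and classification against internal
    controls), measures colony size and reporter fluorescence on an inferred
    colony grid, makes growth/no-growth calls and extracts lag times from
    OD600 time series, quantifies sporulation efficiency and spore counts
    from serial-dilution CFU spots and outgrowth lag calibrations, compares
    two proteomes gene by gene, and generates synthetic plates, growth
    curves and spot counts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    igraph,
    stats,
    utils,
    grDevices,
    tools,
    png,
    tiff
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
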