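Package: cycloc
Title: Colocalization and Reproducibility Analysis for Cyclic Multiplexed
    Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-round, multi-channel fluorescence
    images produced by cyclic immunolabeling of resin-embedded specimens.
    Provides a synthetic scene simulator with stochastic per-round epitope
    labeling, rolling-ball background subtraction, phase-correlation
    registration of imaging rounds, minmax shared/difference decomposition
    of round pairs with Pearson correlation and log-ratio histograms,
    antibody elution efficiency estimation, pixel-occupancy colocalization
    statistics (Otsu and percentile thresholding, 2^k joint-occupancy
    contingency tables, chi-squared tests of mutual independence,
    threshold-sweep exceedance-ratio curves), and depth profiling of label
    intensity against distance from the specimen exterior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
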