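Package: isoclustr
Title: Prediction, Detection, and Validation of Isotope Clusters in LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exhaustive detection and mass-specific validation of
    isotope clusters in liquid chromatography-mass spectrometry (LC-MS) data.
    Predicts isotope regions of interest (ROIs) from a detected peak table for
    targeted peak picking at a relaxed signal-to-noise threshold, detects
    putative isotope clusters from characteristic m/z spacings, and validates
    clusters against mass-window confidence intervals of monoisotopic-to-isotope
    abundance ratios derived from molecular-formula database statistics.
    Includes theoretical isotope pattern computation by isotope-distribution
    convolution with centroid merging, quantile-table construction and lookup,
    performance metrics (isotope coverage, peak picking score), and synthetic
    LC-MS data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
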