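Package: porequal
Title: Image-Quality Metrics and Morphometry for NanoCT Volumes of Porous
    Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Operator-free quantitative evaluation of reconstructed 3D
    tomographic volumes of two-phase mineralized biomaterials. Computes
    per-pore spatial resolution as the full width at half maximum of the
    blurring Gaussian, obtained from the edge-spread (step-up) curve across
    each closed pore-scaffold interface fitted with an error-function
    model, and per-pore signal-to-noise ratio from erosion-cleaned phase
    regions. Includes closed-pore selection by size and sphericity,
    three-phase scaffold morphometry (specific surface area with and
    without closed porosity, mineralized-tissue surface coverage), a
    seeded synthetic phantom generator with known ground truth for
    validation, and volume I/O for TIFF stacks and raw binaries with JSON
    sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
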