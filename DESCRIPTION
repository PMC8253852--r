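Package: octlivewire
Title: Semi-Automatic Live-Wire Segmentation of Retinal Layers and Fluid in
    OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-based semi-automatic segmentation of retinal layer
    boundaries and fluid pockets in optical coherence tomography (OCT)
    B-scans. Boundaries are traced as minimum-cost paths (Dijkstra
    shortest-path-first, the live-wire formulation) through anchor points,
    over boundary-specific cost images built from polarity-aware vertical
    gradients, morphological cleaning and region-of-interest masking.
    Includes a grid-based point-interpolation fallback, peripapillary
    flattening with vessel-shadow removal, closed-contour fluid delineation,
    agreement metrics (unsigned boundary error, irregularity index, Dice,
    Bland-Altman), a layered-phantom generator with exact ground truth and
    simulated clicks, readers for Spectralis VOL volumes and image stacks,
    and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    Rcpp,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
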