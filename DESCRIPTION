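Package: spheromech
Title: Spheroid Morphometry and Quantitative Micro-Elastography on
    Stiffness-Gradient Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tumour spheroids cultured in linear
    stiffness-gradient hydrogels. Calibrates the position-to-stiffness map
    from AFM indentation force curves (pyramidal Sneddon contact model),
    performs 3D voxel-based morphometry of spheroids and nuclei from
    multichannel fluorescence z-stacks (Gaussian-weighted median prefilter,
    F-actin spheroid gating, marker-controlled watershed), quantifies
    mechanomarker expression and nuclear/cytoplasmic ratios with trend
    fitting against stiffness and spheroid volume, and reconstructs
    quantitative micro-elastography (QME) elastograms from wrapped OCT
    phase-difference B-scans via weighted-least-squares strain estimation
    and compliant-layer stress calibration. Every stage is paired with a
    seeded synthetic-data generator emitting ground truth, so the full
    chain is testable without experimental images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
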