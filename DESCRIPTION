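Package: perivasc
Title: Quantification of Perivascular Oligodendrocyte-Vessel Association in 3D Fluorescence Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spatial association of oligodendrocyte cell
    bodies with the brain vasculature in multi-channel 3D fluorescence image
    stacks. Provides a seeded synthetic-volume generator with analytic ground
    truth (vessel networks, marker shells, somata, myelin texture, PSF blur and
    shot noise), vessel segmentation with centerline/radius extraction, per-soma
    peak-to-peak distance measurement and vessel-caliber classification, a
    channel-flip chance-association null, depth-resolved density statistics,
    and passive membrane-property extraction from patch-clamp sweeps including
    Nernst equilibrium potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
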