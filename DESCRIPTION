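Package: polent
Title: Polarimetric Entropy Analysis for Polarization-Sensitive OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify tissue depolarization in polarization-sensitive
    optical coherence tomography (PS-OCT). Converts per-voxel Jones matrices to
    noise-bias-corrected polarimetric entropy via eigen-decomposition of locally
    averaged coherency matrices, segments retinal surfaces (ILM, RPE,
    chorioscleral interface), builds layer-resolved en-face entropy maps,
    extracts ETDRS-grid sector statistics, computes B-scan metrics of the RPE
    entropy-signal area and hyperreflective-foci counts, and provides
    longitudinal nonparametric statistics. A synthetic layered-eye phantom
    generator with analytically known per-layer entropy supports validation in
    place of patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
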