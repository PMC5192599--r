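Package: fishspot
Title: Automated Single-Molecule FISH Quantification for Plant Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated quantification of single-molecule fluorescence in situ
    hybridization (smFISH) images of plant tissue. Segments fields of view into
    cells by seeded watershed, using nuclear-stain (DAPI) derived seeds and the
    probe-channel autofluorescence as the flooding surface; detects
    diffraction-limited mRNA spots on edge-filtered maximum-intensity
    projections with two-pass normalized cross-correlation template matching;
    assigns spots to cells, classifies transcriptionally active cells from
    nuclear nascent-transcript foci, and summarizes transcript counts per cell
    across the population. Includes probe-table validation, a synthetic
    fluorescence-scene generator with ground truth for end-to-end testing and
    correlation-threshold calibration, and annotated-overlay outputs for
    quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
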