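Package: rtmc
Title: Map/Reduce Monte Carlo Dose Verification for Radiotherapy Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for Monte Carlo verification of radiotherapy
    treatments. Reads DICOM RT plans and discretizes dynamic techniques
    (mArc arclets, step-and-shoot IMRT) into static beams, converts CT image
    series into voxelized material/density phantoms via user-defined
    Hounsfield-unit conversion tables (with egsphant and PenVox writers),
    binds beam geometry, histories and random seeds into parametrized Monte
    Carlo input templates, distributes beams over worker processes
    (map), statistically merges binary dose, column-tally and phase-space
    outputs with history-weighted uncertainty propagation (reduce), exports
    merged dose as DICOM RTDOSE, rasterizes RTSTRUCT contours and computes
    dose-volume histograms and dose metrics. Ships a minimal voxel
    ray-attenuation dose engine honoring the same template contract, and
    seed-deterministic synthetic DICOM fixture generators for three
    treatment techniques.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    yaml,
    jsonlite,
    ggplot2,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
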