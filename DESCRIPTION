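Package: sniffglm
Title: Breathing-Modulated Design Matrices and GLM Statistics for Olfactory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing task fMRI of olfaction with designs that are
    modulated by the participant's own breathing. Extracts inhalation events
    from respiratory belt recordings (median filtering, iterative amplitude
    normalization, prominence-based peak detection), builds standard and
    inhalation-modulated block-design matrices on the acquisition grid with a
    dual-gamma hemodynamic model, computes design efficiency, fits run-,
    subject- and group-level general linear models with FDR thresholding,
    Hedge's g effect-size maps and per-voxel winner maps, estimates block-wise
    habituation amplitudes, and simulates breathing traces and
    inhalation-locked BOLD runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
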