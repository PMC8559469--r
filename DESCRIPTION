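Package: geodeface
Title: Geometry-Preserving Deidentification of Anatomical MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes facial and ear features from T1-weighted anatomical MRI
    volumes while preserving the geometry needed for downstream analyses such
    as EEG/MEG forward modeling. A marker-based watershed segmentation yields
    skin and skull surfaces; face and ear control points (template-registered
    or manually supplied) restrict the mask to the skull-to-skin soft-tissue
    shell, which is refilled with draws from the shell's own empirical
    intensity distribution; voxels outside the skin surface are zeroed.
    Includes geometric evaluation metrics (Jaccard overlap, symmetric
    Hausdorff distance between triangulated surfaces, automated surface
    usability screening) and a synthetic layered head phantom with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
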