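Package: orgseg
Title: Multi-Organ CT Segmentation and PET Quantification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deep-learning-based multi-organ segmentation of 3D
    computed tomography (CT) volumes and quantification of co-registered
    positron emission tomography (PET) images. Implements a 100-organ label
    registry (77 bones, 23 soft-tissue organs), Hounsfield-unit normalisation
    and grid resampling, patch sampling with sparse-annotation masking and
    augmentation, two small fully convolutional networks (a semantic network
    and a vertebra/rib instance network with per-voxel centre regression),
    single-linkage clustering of predicted centres into numbered vertebrae and
    ribs, morphological postprocessing (largest connected component, hole
    filling), Dice/recall/precision evaluation with group aggregation,
    per-label quantification including body-weight standardised uptake values
    (SUV) and total lesion uptake, DICOM and NIfTI readers/writers, DICOM
    de-identification, and a synthetic CT/PET phantom generator so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
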