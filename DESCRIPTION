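Package: ElecLoc
Title: Localization, Anatomical Labeling and Atlas Warping of Intracranial
    Electrodes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for localizing intracranial (ECoG and stereo-EEG)
    electrodes from a postoperative CT coregistered to a preoperative T1
    MRI, labeling them against cortical and subcortical parcellations, and
    warping them to a template brain. Provides rigid CT-to-MRI registration
    by normalized mutual information, bilinear interpolation of high-density
    grids from four corner electrodes, projection of subdural electrodes to
    a smoothed dural surface, nearest-vertex and parcellation-voxel
    anatomical labeling, spherical-correspondence surface warping and dense
    displacement-field depth warping with label-agreement quality control,
    and marching-tetrahedra extraction of subcortical meshes. Ships
    deterministic synthetic phantoms (head volumes, deformed-sphere pial
    meshes, blob parcellations, smooth warp fields) so the full pipeline is
    testable without scanner data or an external surface-reconstruction
    suite, plus a subject-directory pipeline driver and headless QC
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
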