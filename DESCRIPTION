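Package: ctmotion
Title: CT-Based Measurement of Load-Induced Tibial Implant Displacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures rigid displacement of a tibial knee implant relative to
    the tibia from paired CT scans acquired under valgus and varus loading.
    Segments implant and cortex by threshold-connected region growing with
    Laplacian level-set refinement, extracts marching-cubes surface meshes,
    builds a double-contour gray-value feature, and registers each object into
    the second scan by Nelder-Mead maximisation of the gray-value correlation.
    Relative displacements are expressed in an automatically constructed
    implant coordinate system and summarised as translation/rotation
    magnitudes, mean target registration error (mTRE) and maximum total point
    motion (MTPM). A synthetic tibia-plus-implant CT phantom generator with
    exactly known ground-truth bending and implant micro-motion supports
    validation experiments: methodological error from repeat scans, tibia
    deformation under load, and implant displacement relative to the whole
    versus the proximal tibia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    RANN,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
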