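Package: fetalkick
Title: Biomechanics of Fetal Kicks from Cine-MRI-Like Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the biomechanics of fetal kicking movements in
    utero. Generates ground-truthed synthetic cine-MRI-like kick sequences,
    tracks hip, knee and ankle joints with accumulated recency-weighted
    template matching under segment-length constraints, computes uterine-wall
    reaction forces with a 2D plane-stress finite-element indentation model
    (bilayer elliptical wall, frictionless penalty contact, geometric
    nonlinearity), and predicts per-muscle forces with a planar
    musculoskeletal model (scaling, inverse kinematics, inverse dynamics with
    gravity neglected, and quadratic static optimization with reserve
    actuators). Includes an end-to-end pipeline over per-fetus scenarios and
    cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
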