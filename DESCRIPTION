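Package: cochreg
Title: Landmark-Based Affine Registration of a Parametric Cochlear Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a parametric model of the human cochlea to ordered 3D
    landmarks extracted from conventional computed tomography. Provides the
    spiral centerline model with quadrant parameters (A_a, A_b, B_a, B_b),
    angular landmark-placement schemes, quadrant-parameter estimation from
    basal chords, a 12-parameter affine registration (rotation, translation,
    anisotropic scaling, shearing, optional reflection) minimised by a
    quasi-Newton method on the sum of squared landmark distances, iterative
    worst-landmark pruning with mean-absolute-error reporting, and a
    synthetic phantom generator with CT-resolution voxel quantization noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
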