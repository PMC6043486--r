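Package: radnorm
Title: Voxel-Size and Gray-Level Normalization of CT Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of 24 intensity and texture radiomic features
    (intensity histogram, GLCM, GLRLM, GLSZM, NGTDM) from 3D image volumes
    with binary volumes of interest, together with the voxel-size and
    gray-level normalizations that remove the intrinsic dependence of these
    features on the number of voxels and on the number of discretization
    levels. Includes trilinear resampling to arbitrary pixel size and slice
    thickness, equispaced gray-level discretization, Spearman and
    intraclass-correlation robustness analyses, and a synthetic-data
    generator emulating lung-tumor cohorts and homogeneous texture phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
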