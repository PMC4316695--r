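Package: dvfqa
Title: Quality Assurance Metrics for Deformable Image Registration Vector Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-by-voxel comparison tools for deformable image registration
    (DIR) quality assurance. Computes Jacobian-determinant maps of dense
    displacement vector fields (DVFs) with the unity edge convention, spatial
    discrepancy maps between pairs of DVFs, volume-weighted Jacobian and
    spatial-discrepancy volume histograms (JVH/SDVH) with weighted mean,
    standard deviation and fractional-volume tail boundaries, DICE-based
    contour propagation checks, and cohort-level paired t-test summaries.
    Includes a synthetic-deformation generator with closed-form Jacobians,
    phantom organ masks and injectable folding defects so every statistic can
    be validated against an analytic ground truth, plus readers and writers
    for NIfTI and MetaImage vector volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tidyr
Config/testthat/edition: 3
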