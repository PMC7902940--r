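Package: morphoquant
Title: Immunohistochemistry Signal Quantification and Deformation-Based
    Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for brightfield immunohistochemistry and
    small-animal brain morphometry cohort studies. Implements per-image
    background thresholding at the histogram mode minus a fixed multiple of
    the whole-image standard deviation, percent-positive area per region of
    interest, size-filtered counting of stained cell bodies, structure
    volumetrics by integrating Jacobian-determinant deformation maps over a
    label atlas with whole-brain normalization, per-sex voxel-wise linear
    models with Benjamini-Hochberg false-discovery-rate control, and two-way
    sex-by-genotype analysis of variance. Ships seeded synthetic-data
    generators with ground truth so every stage is testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    png,
    tiff,
    RNifti,
    jsonlite,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
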