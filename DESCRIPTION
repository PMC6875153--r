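Package: stngrad
Title: Gradient and Subdivision Models for 3D Subthalamic Nucleus
    Immunoreactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for deciding whether protein-marker
    immunoreactivity in a 3D reconstruction of the human subthalamic
    nucleus (STN) is organized as a homogeneous field, a linear gradient,
    three discrete subdivisions, or a smooth sigmoidal gradient. Provides
    mask-normalized Gaussian smoothing of thresholded staining volumes,
    PCA-based anatomical axes, equal-volume sector rasterization,
    across-specimen sector consistency testing with false discovery rate
    control, maximum-likelihood fitting of four negative-binomial spatial
    generalized linear models by differential evolution with local
    refinement, BIC/weighted-BIC model comparison and preference tallies,
    and a seeded synthetic-study generator so every stage is testable
    without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
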