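Package: depthIEM
Title: Inverted Encoding Models for Horizontal and Depth Position from
    Trial-Wise fMRI Responses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of fMRI population codes for stimulus
    position along the horizontal (x) and depth (z) axes of a rendered
    stereoscopic scene. Provides the stereo viewing geometry (eccentricity
    and binocular disparity of scene points), a staggered triangular
    stimulus grid, generation of synthetic voxel datasets with known
    spatial tuning (optionally as HRF-convolved time series), an inverted
    encoding model with an exponentiated-cosine channel basis and
    leave-one-run-out cross-validation, constrained grid-plus-refinement
    curve fitting of model-based representations, pairwise linear-SVM
    decoding scored by d-prime with permutation nulls and FDR control,
    and bootstrap resampling across subjects for confidence intervals and
    center-versus-true slope estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
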