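Package: fixdur
Title: Fixation-Duration Analysis for Scene Viewing with Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for analysing eye-fixation durations during real-world
    scene viewing. Computes five local image-feature maps per scene (CIELab
    luminance, Sobel edges, feature-congestion visual clutter, and a mean-shift
    image segmentation), extracts local statistics from 1-degree circular
    patches centred on fixation locations, assembles fixation triplets
    (previous, current, next) with oculomotor and spatiotemporal covariates,
    and fits zero-correlation-parameter linear mixed models with crossed
    subject and scene random effects to test immediacy, lag and successor
    effects of local image features on log fixation durations. Includes a
    synthetic-data generator (dual Latin-square design, scene synthesis,
    scanpath simulation, log-normal durations from a known generative model)
    for end-to-end validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    lme4,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
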