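Package: SpecFill
Title: Temporal Inpainting of Specular Highlights in Endoscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised removal of specular highlight reflections from
    endoscopic video. Detects saturated highlight regions with a
    chromaticity-based rule, builds pseudo-ground-truth masks by translating
    detections onto unoccluded mucosa, and inpaints the holes with a
    spatial-temporal transformer generator trained adversarially against a
    spatio-temporal patch discriminator. Ships classic diffusion and
    patch-search baselines, masked image-quality metrics with two-level
    averaging, stereo disparity error metrics, and a sparse-feature /
    relative-pose harness (binary descriptor matching, five-point essential
    matrix estimation with RANSAC and chirality checks) for quantifying the
    downstream effect of inpainting on image correspondence. A seeded
    synthetic-endoscopy generator provides clips, two-view scenes and stereo
    pairs with exact ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    Matrix,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
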