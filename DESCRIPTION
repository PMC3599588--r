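Package: v1sal
Title: Two-Layer V1-Inspired Bottom-Up Visual Saliency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biologically constrained two-layer model of bottom-up visual
    attention. Layer one is an overcomplete set of Gabor-like filters learned
    from image patches by a topographic ICA-style rule on a torus grid; layer
    two pools rectified filter responses over refined topographic
    neighbourhoods into invariant feature maps, which compete through
    non-classical-receptive-field surround suppression (difference-of-Gaussians
    inhibition) and are combined into a single saliency map by iterative
    sharpening, K-means clustered combination, or sum/max baselines. Includes
    comparison network variants (no-invariance, fully connected, randomly
    connected), generators for the classic visual-search and contour
    psychophysics stimuli with machine-readable ground truth, and evaluation
    metrics (correct detection rate, top-m segment criterion with binomial
    chance level, ROC area against fixation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tibble,
    png,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
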