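Package: retvessel
Title: Multilevel Otsu Segmentation of Retinal Vessel Images with a
    PSO-Improved Salp Swarm Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of retinal fundus vessel images by
    multilevel Otsu thresholding. Vessels are enhanced with an oriented
    Gaussian matched-filter bank fused with a morphological top-hat/bot-hat
    detail image; optimal gray-level thresholds are then found by maximizing
    the between-class variance with a salp swarm algorithm whose leader
    step-length coefficients are synthesized by an inner particle swarm
    (PMSSA). Plain particle swarm and multi-salp-swarm searches and an exact
    brute-force/dynamic-programming oracle are included for comparison, along
    with ten segmentation quality indicators (PSNR, SSIM, FSIM, Dice, Jaccard,
    sensitivity, specificity, accuracy, Shannon entropy, region uniformity)
    and a seeded synthetic vessel-phantom generator with ground-truth masks
    so the whole pipeline is testable without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
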