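Package: lungct
Title: Lung-CT Tumor Segmentation and Classification on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale intelligent system for lung computed-tomography
    image analysis: synthetic CT-like phantom generation with ground-truth
    tumor masks, noise-removal filtering (average, median, adaptive median)
    and histogram equalization, patch-wise tumor segmentation with a deep
    belief network built from Gaussian-Bernoulli and Bernoulli-Bernoulli
    restricted Boltzmann machines, a fixed 50-feature descriptor of the
    segmented region, hybrid spiral-optimization / rough-set feature
    selection, and a gradient-boosted decision-tree classifier with
    gradient-based one-side sampling tuned by a Harris-hawks optimizer.
    Includes confusion-matrix metrics, ROC/AUC, and an end-to-end seeded
    pipeline with per-stage ablation toggles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
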