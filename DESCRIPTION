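Package: wavevit
Title: Wavelet-Fusion Vision Transformer for Semi-Supervised Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Four-class classification of panoramic maxillofacial radiographs
    with a Vision Transformer augmented by a wavelet extraction-and-fusion
    module. Provides orthonormal single-level Haar decomposition with
    per-sub-band convolutional fusion and exact inverse reconstruction, a
    compact transformer classifier with hand-written analytic gradients,
    masked-autoencoder domain-adaptation pre-training on healthy images,
    semi-supervised training with self-adaptive pseudo-label thresholds,
    stratified k-fold evaluation with one-vs-rest clinical metrics and
    Grad-CAM relevance maps, and a seeded synthetic radiograph generator so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
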