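Package: octfirefly
Title: Hierarchical Retinal OCT Classification with Binary Firefly Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid pipeline for classifying retinal disease in optical
    coherence tomography (OCT) B-scans: retinal-layer masking (bilateral
    filter, CLAHE, Otsu thresholding, morphological cleaning), hybrid
    feature extraction (gray-level co-occurrence statistics, histograms of
    oriented gradients, and pluggable headless convolutional embeddings),
    wrapper feature selection by a binary firefly algorithm with a
    K-nearest-neighbour fitness, and a hierarchy of binary classifiers
    (abnormal/normal, AMD/DME, CNV/DRUSEN) with full confusion-matrix
    metrics. Includes a seeded synthetic OCT phantom generator with known
    lesion ground truth so the whole pipeline is testable without external
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    e1071,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jpeg,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
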