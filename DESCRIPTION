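Package: leafproto
Title: Interpretable Prototypical-Part Classification of Crop Leaf Disease Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An intrinsically interpretable image classifier for crop leaf
    disease and pest recognition. Images are scored by the similarity between
    latent convolutional feature patches and learnable class prototypes; a
    linear head turns maximal per-prototype similarities into class logits, so
    every prediction decomposes exactly into per-prototype evidence
    (activation maps, source patches, weighted similarity contributions).
    Training combines cross-entropy with cluster, separation and supervised
    contrastive losses (momentum key encoder with a FIFO dictionary), and a
    projection ("push") step ties every prototype to a real training patch.
    Includes a synthetic leaf-lesion image generator with ground-truth lesion
    masks, the offline augmentation pipeline (skew, shear, elastic distortion,
    flip, HSV jitter), evaluation metrics (confusion matrix, one-vs-rest
    ROC/AUC, k-fold cross-validation) and machine-readable reasoning reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
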