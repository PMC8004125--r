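Package: ceusfuse
Title: Multimodal Fusion Classification of Liver Tumors in Paired B-Mode and
    Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for distinguishing hepatocellular carcinoma (HCC) from
    cirrhotic liver parenchyma in co-registered pairs of B-mode and
    contrast-enhanced ultrasound (CEUS) images. Provides paired-patch
    preparation from polygon-annotated image pairs (VIA-style JSON
    annotations, 51x51 regions of interest, strict inside/outside labeling),
    three levels of modality fusion (pixelwise feature-level fusion,
    classifier-level fusion of CNN branch feature vectors with optional
    kernel PCA, and decision-level averaging of class probabilities), a
    41-feature generalized co-occurrence texture baseline with
    correlation-based and gain-ratio feature selection, a compact CNN engine
    with shape-faithful backbone registries, ROC/AUC evaluation, and a seeded
    synthetic generator of paired-modality patches and annotated frames so the
    whole pipeline is testable without private patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png,
    nnet,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC
Config/testthat/edition: 3
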