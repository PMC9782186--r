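Package: transferscope
Title: Transfer Evaluation of Image Feature Extractors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well a frozen image feature extractor
    transfers to a labeled image classification task. Implements episodic
    few-shot evaluation with prototypical networks, many-shot evaluation via
    an l2-regularized multinomial logistic-regression linear probe and an
    SGD finetuning protocol with early stopping, occlusion-based saliency
    maps with the attentive-diffusion statistic, and transformation-invariance
    scores based on whitened cosine similarity (including a multi-view
    variant). A synthetic image generator with planted class textures makes
    every stage testable without external datasets or pretrained weights, and
    dataset adapters convert common medical-imaging label schemes
    (many-to-one binarization, abnormal-vs-normal, class merging, ordinal
    encoding, single-pathology filtering) into classification-ready labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    glmnet,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
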