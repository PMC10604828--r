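Package: histotune
Title: Metaheuristic Hyperparameter Search for Transfer-Learning
    Histopathology Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Population-based hyperparameter optimization for binary
    histopathology image classification. Implements the Aquila Optimizer
    and the artificial Gorilla Troops Optimizer over a normalized unit
    hypercube encoding of a mixed categorical/continuous transfer-learning
    configuration space, together with the surrounding pipeline: bicubic
    image resizing, four per-image scaling transforms, augmentation-based
    class balancing, nested train/validation/test partitioning, pluggable
    fitness backends (an analytic surrogate and a small trainable
    classifier), and a twelve-metric confusion-count evaluation suite with
    a weighted-sum combiner. A seeded synthetic image generator makes the
    whole pipeline runnable at desk scale without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
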