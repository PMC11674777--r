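Package: cuckoofuse
Title: Adaptive-Weight Ensemble Fusion of Classifier Probabilities via Cuckoo Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fuses per-sample class-probability outputs of multiple
    classifiers by simple or weighted soft voting, with fusion weights
    selected by a Cuckoo Search optimizer driven by Levy flights.
    Includes the evaluation suite used for ordinal dementia-severity
    staging (per-class and micro-averaged precision/recall/F1, micro
    ROC-AUC, Scott's Pi agreement with optional ordinal weighting), a
    class-imbalance protocol (test-set reservation, combined under- and
    oversampling to a per-class target, stratified train/validation
    splitting), and a synthetic-prediction generator with controllable
    model skill and inter-model error correlation, so the whole workflow
    is exercisable without image data or trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
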