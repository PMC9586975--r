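Package: stackbox
Title: Stacked Meta-Regression Ensembles for Bounding-Box Object Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses the bounding-box predictions of several object detectors
    into a single refined detection set by stacking: a per-coordinate
    meta-regression is trained on base-learner boxes matched to ground
    truths, then applied to pooled test-time predictions. Includes the
    standard box-fusion baselines (non-maximum suppression, Soft-NMS,
    non-maximum weighted fusion, and weighted boxes fusion), a COCO-style
    average-precision and average-recall evaluation suite with 101-point
    interpolation, a seeded synthetic-scenario generator that simulates
    biased and noisy base learners, COCO-format JSON readers and writers,
    and a cross-validation harness. Developed for polyp detection in
    colonoscopy imagery but applicable to any axis-aligned detection task.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'geometry.R'
    'tables.R'
    'AllClasses.R'
    'fusion.R'
    'train.R'
    'infer.R'
    'io.R'
    'metrics.R'
    'stackbox-package.R'
    'synthetic.R'
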