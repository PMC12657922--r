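Package: lagLayer
Title: Lag-Resolved Layer-Wise Encoding Models for Intracranial Neural
    Recordings
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies whether deeper layers of a layered word-embedding
    model peak later in time in neural recordings. Implements lag-wise
    cross-validated linear encoding models on high-gamma band power around
    word onsets, per-layer fold-safe dimensionality reduction, the
    lag-layer correlation statistic with exact, permutation and
    interpolation-based inference, phase-randomization electrode
    selection with false-discovery-rate control, symbolic psycholinguistic
    feature embeddings, and a synthetic-data generator with planted
    lag-layer gradients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'lagLayer-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'encoding.R'
    'stats.R'
    'controls.R'
    'embeddings.R'
    'preprocess.R'
    'synthetic.R'
    'io.R'
    'symbolic.R'
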