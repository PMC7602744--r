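Package: hostclass
Title: Cross-Study Host Classification of Gut Microbiome Samples
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pet/human host classifiers from genus-level 16S rRNA
    feature tables pooled across independent studies. Provides taxonomy
    aggregation and rare-feature filtering, Chao1 richness under repeated
    fixed-depth subsampling, project-median Mann-Whitney differential
    abundance with Holm and Benjamini-Hochberg control, centred log-ratio
    transformation and Bray-Curtis dissimilarity, host- and
    project-balanced dataset construction, a two-step random-forest
    hyperparameter search with out-of-bag evaluation, and a project
    learning curve that quantifies study-level overfitting. A synthetic
    multi-project count-table generator with planted host effects,
    host-exclusive taxa and per-study batch effects supports calibration
    and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    graphics,
    jsonlite,
    ranger,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
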