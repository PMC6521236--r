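Package: fcpcomm
Title: Functional Gene-Based Prediction of Microbial Community Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models microbial community composition with replicator dynamics
    under variable population size, quantifying fitness from inter-species
    functional-gene dissimilarity (COG hit-count profiles) plus environmental
    filtering learned by Lasso regression. Provides steady-state prediction and
    cross-validation of compositions, an in-silico knockout screen for
    community structure shaping (CSS) genes calibrated against a
    perturbation null, category enrichment and gene-set overlap tests, and a
    synthetic-community generator with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'interaction.R'
    'dynamics.R'
    'fitting.R'
    'css.R'
    'synthetic.R'
    'config.R'
    'cli.R'
    'fcpcomm-package.R'
    'io.R'
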