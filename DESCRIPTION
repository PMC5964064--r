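Package: multitaskSparsity
Title: Robustness of Multitask Activity Prediction to Missing Training Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks how multitask compound-activity prediction degrades
    as training matrices are made progressively sparser. Provides S4
    containers for compound-by-assay activity matrices with explicit
    observed-cell masks and for hashed binary fingerprints; a synthetic-data
    generator emulating a kinase percent-inhibition panel and binary
    high-throughput-screening profiles; three data-removal models (individual
    labels, whole compounds, whole assays); three multitask predictors
    (Bayesian probabilistic matrix factorization with fingerprint side
    information fitted by Gibbs sampling, a masked-loss fully connected
    neural network trained with Adagrad, and a per-assay random-forest
    baseline with assay-mean imputation); per-assay regression and
    classification metrics; and an orchestrator that sweeps removal-fraction
    grids, aggregates median scores relative to the complete-data model and
    locates the removal fraction at which performance degrades by a chosen
    amount.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ranger,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'data_core.R'
    'bpmf.R'
    'sparsify.R'
    'experiment.R'
    'forest_baseline.R'
    'metrics.R'
    'neural_multitask.R'
    'plots.R'
    'synthetic_data.R'
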