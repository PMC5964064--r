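# multitaskSparsity

Benchmarks how multitask compound-activity prediction degrades as the
training matrix is made progressively sparser.

## Background

Drug-discovery panels measure compounds against many related assays at once,
giving a compounds × assays *activity matrix*. Multitask methods exploit the
correlation between assays, so a natural question is how much of the matrix
can be missing before predictions collapse — and whether it matters *how* the
data go missing. This package provides everything needed to study that
question on synthetic data with known ground truth:

- **Data containers.** S4 classes `ActivityMatrix` (values plus an explicit
  observed-cell mask; regression or binary classification task types) and
  `FingerprintSet` (hashed binary substructure fingerprints), with CSV
  round-trip IO and validity checking.
- **A synthetic generator.** Low-rank compound × assay signal with clustered
  assays, optional dependence of activity on the fingerprints, calibrated
  noise, and presets emulating a kinase percent-inhibition panel
  (`pkis_like`: 367 × 454, values roughly in [−77, 130] with ~80% in
  [0, 100]) and binary screening profiles (`htsfp5_like`, `htsfp10_like`).
- **Three removal models.** `removeLabels` deletes individual cells (matrix
  size kept), `removeCompounds` deletes whole rows, `removeAssays` whole
  columns; each removes exactly `round(f * L)` of the relevant units.
- **Three predictors.** `bpmfFit` — Bayesian probabilistic matrix
  factorization with fingerprint side information folded into the compound
  prior mean (Gibbs sampling, Normal–Wishart hyperpriors), which predicts
  unseen (cold-start) compounds through the fingerprint link; `nnFit` — a
  fully connected multitask network with a masked loss so unobserved cells
  contribute nothing to training; `forestFit` — a per-assay random-forest
  baseline that requires a complete matrix and is therefore valid only under
  compound removal.
- **Metrics and orchestration.** Per-assay RMSD/MAE/R²/ρ² and
  precision/recall/F1/MCC, medians across assays relative to the
  complete-data model, threshold-crossing detection, and `runExperiment`,
  which sweeps a (method × removal model × fraction × seed) grid into a
  deterministic, resumable long-form CSV.

## Quick start

```r
library(multitaskSparsity)

# a kinase-panel-like dataset, scaled down
cfg <- syntheticPreset("pkis_like", nCompounds = 150, nAssays = 100)
panel <- genRegressionMatrix(cfg)
panel$activity
#> ActivityMatrix (regression): 150 compounds x 100 assays, 14992 observed (99.95% filled)

# hold out 25% of compounds, then delete 50% of the remaining labels
split <- trainTestSplit(panel$activity, testFraction = 0.25, seed = 1)
sparse <- removeLabels(split@train, fraction = 0.5, seed = 1)
fillFraction(sparse)
#>  percentFilled percentMissing
#>       49.97321       50.02679

fpsTrain <- FingerprintSet(fingerprintBits(panel$fingerprints)[compoundIds(split@train), ])
fpsTest  <- FingerprintSet(fingerprintBits(panel$fingerprints)[compoundIds(split@test), ])

fit <- bpmfFit(sparse, fpsTrain, latentDim = 8, nSamples = 60, burnIn = 40, seed = 1)
fit
#> BPMFTrace: 60 samples (burn-in 40), k = 8, 100 assays, regression task

pred <- predictActivity(fit, fpsTest)     # cold-start via the fingerprint link
scores <- scorePredictions(split@test, pred)
head(scores, 3)
#>     assay_id  n     rmsd       mae         r2       rho2
#> 1 assay_0001 38 22.19471 16.594325 0.19884106 0.23677863
#> 2 assay_0002 38 12.67436  9.101599 0.01655003 0.06042817
#> 3 assay_0003 38 37.89913 26.693701 0.01375075 0.11995657
median(scores$rmsd)
#> [1] 36.28535
```

A full degradation sweep is one call:

```r
spec <- runSpec("pkis_like",
                datasetArgs  = list(nCompounds = 150, nAssays = 100),
                methods      = list(bpmf = list(list(latentDim = 8))),
                removalModels = "label",
                fractions    = c(0, 0.25, 0.5, 0.75, 0.9),
                splitSeeds   = 1:4, removalSeeds = 1:4)
results <- runExperiment(spec)
report  <- reportCurves(results, metric = "rmsd")
report$knees                     # first fraction with >= 10% degradation
plotProgression(report)          # relative-performance curves
```

Run specs can also be read from YAML with `readRunSpec()`. Cells whose
sparsified training matrix ends up with empty assays or compounds are
recorded as status rows (`empty_assay`, `empty_compound`, `fit_failed`)
rather than aborting the sweep, and an interrupted run resumes where it
stopped.

## License

MIT (see `LICENSE`).
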