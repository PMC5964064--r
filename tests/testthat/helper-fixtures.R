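# Small fixtures built in code.

# deterministic tiny activity matrix with an explicit missing cell
tinyActivity <- function(taskType = "regression") {
  if (taskType == "regression") {
    v <- matrix(c(1.5, NA, 3, -2, 0, 10), 3, 2,
                dimnames = list(c("c1", "c2", "c3"), c("a1", "a2")))
  } else {
    v <- matrix(c(1, NA, 0, 0, 1, 1), 3, 2,
                dimnames = list(c("c1", "c2", "c3"), c("a1", "a2")))
  }
  ActivityMatrix(v, taskType = taskType)
}

# random fully observed matrix with paired fingerprints
smallDataset <- function(n = 30, m = 5, seed = 1, taskType = "regression", ...) {
  if (taskType == "classification") {
    cfg <- syntheticConfig(nCompounds = n, nAssays = m, nBits = 128L,
                           bitsSetRange = c(10L, 20L, 40L), tanimotoTarget = 0.1,
                           targetActiveRatios = rep(1, m),
                           missingFraction = 0, seed = seed, ...)
    genClassificationMatrix(cfg)
  } else {
    cfg <- syntheticConfig(nCompounds = n, nAssays = m, nBits = 128L,
                           bitsSetRange = c(10L, 20L, 40L), tanimotoTarget = 0.1,
                           missingFraction = 0, seed = seed, ...)
    genRegressionMatrix(cfg)
  }
}

# fingerprints with the row order of an activity matrix subset
alignFps <- function(fps, am) {
  FingerprintSet(fingerprintBits(fps)[compoundIds(am), , drop = FALSE])
}

heldOutRmsd <- function(pred, truthMat, mask) {
  sqrt(mean((pred[mask] - truthMat[mask])^2))
}
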