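# Helper: trace with hand-specified snapshots for prediction arithmetic.
manualTrace <- function(samples, assayNames, trainIds, center = 0, scale = 1) {
  new("BPMFTrace", samples = samples, center = center, scaleFactor = scale,
      assayIds = assayNames, taskType = "regression",
      config = list(latentDim = ncol(samples[[1]]$U), nSamples = length(samples),
                    burnIn = 0L, noisePrecision = 5, linkPrecision = 5,
                    seed = 1L, trainCompoundIds = trainIds,
                    objective = numeric(0)))
}

test_that("the regularized objective matches a term-by-term loop", {
  set.seed(5)
  v <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("c", 1:4), paste0("a", 1:3)))
  v[2, 3] <- NA
  am <- ActivityMatrix(v)
  U <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(6), 3, 2)
  lu <- 0.7; lv <- 1.3
  ctr <- mean(v[!is.na(v)])
  # brute-force oracle
  acc <- 0
  for (i in 1:4) for (j in 1:3) {
    if (!is.na(v[i, j])) acc <- acc + ((v[i, j] - ctr) - sum(U[i, ] * V[j, ]))^2
  }
  acc <- acc + lu * sum(U^2) + lv * sum(V^2)
  expect_equal(mapObjective(am, U, V, lu, lv), acc)

  expect_equal(mapObjective(am, U * 0, V * 0, 0, 0),
               sum((v[!is.na(v)] - ctr)^2))                 # zero factors
  # residual-free exact factorization
  ex <- U %*% t(V)
  dimnames(ex) <- dimnames(v)
  amEx <- ActivityMatrix(ex)
  expect_equal(mapObjective(amEx, U, V, 0, 0, center = 0), 0)
})

test_that("predictions are the snapshot average, restored to response units", {
  U1 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("c1", "c2"), NULL))
  V1 <- matrix(c(1, 2, 3, 4), 2, 2)
  U2 <- U1 * 2; V2 <- V1 * 0.5
  beta <- matrix(0, 4, 2)
  s1 <- list(U = U1, V = V1, beta = beta, muU = c(0, 0))
  s2 <- list(U = U2, V = V2, beta = beta, muU = c(0, 0))
  fps <- FingerprintSet(matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L), 2, 4,
                               dimnames = list(c("c1", "c2"), NULL)))
  oneS <- manualTrace(list(s1), c("a1", "a2"), c("c1", "c2"), center = 10, scale = 2)
  expect_equal(predictActivity(oneS, fps),
               U1 %*% t(V1) * 2 + 10, ignore_attr = TRUE)   # mean of one
  twoS <- manualTrace(list(s1, s2), c("a1", "a2"), c("c1", "c2"))
  hand <- (U1 %*% t(V1) + U2 %*% t(V2)) / 2
  expect_equal(predictActivity(twoS, fps), hand, ignore_attr = TRUE)
  expect_error(predictActivity(twoS, fps, assays = "nope"), "unknown assay")
})

test_that("cold-start compounds are predicted through the side-information prior mean", {
  U <- matrix(1, 1, 2, dimnames = list("seen", NULL))
  V <- matrix(c(1, 0, 0, 1), 2, 2)
  beta <- rbind(c(0.5, -0.5), c(1, 1))
  s <- list(U = U, V = V, beta = beta, muU = c(0.25, 0.25))
  trace <- manualTrace(list(s), c("a1", "a2"), "seen")
  fps <- FingerprintSet(matrix(c(1L, 1L), 1, 2, dimnames = list("new", NULL)))
  uNew <- c(0.5 + 1, -0.5 + 1) + 0.25
  expect_equal(predictActivity(trace, fps), matrix(uNew %*% t(V), 1, 2),
               ignore_attr = TRUE)
})

test_that("classification rounding clamps to {0,1} with ties to active", {
  expect_equal(roundToClass(c(0.49, 0.51, -0.3, 1.7, 0.5)), c(0, 1, 0, 1, 1))
})

test_that("a constant training matrix is reproduced via centering", {
  fps <- smallDataset(n = 6, m = 2, seed = 3)$fingerprints
  v <- matrix(7, 6, 4, dimnames = list(rownames(fingerprintBits(fps)),
                                       paste0("a", 1:4)))
  am <- ActivityMatrix(v)
  trc <- bpmfFit(am, fps, latentDim = 2, nSamples = 20, burnIn = 10, seed = 1)
  pred <- predictActivity(trc, fps)
  expect_lt(max(abs(pred - 7)), 0.5)
})

test_that("a small noiseless rank-1 matrix is completed accurately", {
  u <- seq(1, 12); v <- c(2, -1, 3, 1, -2, 1.5)
  vals <- outer(u, v)
  fps <- smallDataset(n = 12, m = 2, seed = 8)$fingerprints
  dimnames(vals) <- list(rownames(fingerprintBits(fps)), paste0("a", 1:6))
  am <- ActivityMatrix(vals)
  tr <- removeLabels(am, 0.2, seed = 5)
  expect_gte(min(rowSums(observedMask(tr))), 2L)   # identifiable per compound
  trc <- bpmfFit(tr, fps, latentDim = 2, nSamples = 150, burnIn = 100,
                 noisePrecision = 50, seed = 3)
  pred <- predictActivity(trc, fps)
  ho <- observedMask(am) & !observedMask(tr)
  expect_lt(heldOutRmsd(pred, vals, ho), 0.05 * diff(range(vals)))
})

test_that("the sampler is reproducible given config and seed", {
  dat <- smallDataset(n = 25, m = 6, seed = 2)
  tr <- removeLabels(dat$activity, 0.2, seed = 1)
  a <- bpmfFit(tr, dat$fingerprints, latentDim = 3, nSamples = 8, burnIn = 4, seed = 9)
  b <- bpmfFit(tr, dat$fingerprints, latentDim = 3, nSamples = 8, burnIn = 4, seed = 9)
  expect_identical(a@samples, b@samples)
  c_ <- bpmfFit(tr, dat$fingerprints, latentDim = 3, nSamples = 8, burnIn = 4, seed = 10)
  expect_false(identical(a@samples, c_@samples))
})

test_that("training data with empty slices error by default and prune on request", {
  dat <- smallDataset(n = 12, m = 4, seed = 4)
  v <- activityValues(dat$activity)
  v[, 2] <- NA
  v[5, ] <- NA
  sparse <- ActivityMatrix(v)
  expect_error(bpmfFit(sparse, dat$fingerprints, latentDim = 2,
                       nSamples = 3, burnIn = 1, seed = 1),
               "assay_0002")
  pruned <- bpmfFit(sparse, dat$fingerprints, latentDim = 2, nSamples = 3,
                    burnIn = 1, seed = 1, emptyAction = "prune")
  expect_equal(length(pruned@assayIds), 3L)
})

test_that("the running-mean objective ends below the zero-factor baseline", {
  dat <- smallDataset(n = 40, m = 10, seed = 6)
  tr <- removeLabels(dat$activity, 0.2, seed = 2)
  trc <- bpmfFit(tr, dat$fingerprints, latentDim = 4, nSamples = 40,
                 burnIn = 10, seed = 5)
  obj <- trc@config$objective
  expect_length(obj, 40L)
  expect_true(all(is.finite(obj)))
  # the posterior mean must explain training variance: masked residuals of
  # its predictions stay below the zero-factor (predict-the-mean) residual
  pred <- predictActivity(trc, dat$fingerprints)
  mask <- observedMask(tr)
  vals <- activityValues(tr)
  residModel <- sum((vals[mask] - pred[mask])^2)
  residZero <- sum((vals[mask] - mean(vals[mask]))^2)
  expect_lt(residModel, residZero)
})

test_that("reconstruction is invariant to a joint rotation of the latents", {
  set.seed(11)
  U <- matrix(rnorm(10), 5, 2); V <- matrix(rnorm(8), 4, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(U %*% t(V), (U %*% R) %*% t(V %*% R), tolerance = 1e-12)
  rownames(U) <- paste0("c", 1:5)
  s1 <- list(U = U, V = V, beta = matrix(0, 3, 2), muU = c(0, 0))
  s2 <- list(U = U %*% R, V = V %*% R, beta = matrix(0, 3, 2), muU = c(0, 0))
  fps <- FingerprintSet(matrix(1L, 5, 3, dimnames = list(paste0("c", 1:5), NULL)))
  p1 <- predictActivity(manualTrace(list(s1), paste0("a", 1:4), rownames(U)), fps)
  p2 <- predictActivity(manualTrace(list(s2), paste0("a", 1:4), rownames(U)), fps)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("real fingerprints beat shuffled fingerprints on cold-start prediction", {
  rmsds <- vapply(1:5, function(s) {
    cfg <- syntheticPreset("pkis_like", nCompounds = 120, nAssays = 60, seed = s)
    out <- genRegressionMatrix(cfg)
    sp <- trainTestSplit(out$activity, seed = s)
    fpsTr <- alignFps(out$fingerprints, sp@train)
    fpsTe <- alignFps(out$fingerprints, sp@test)
    rmsdOf <- function(fps) {
      trc <- bpmfFit(sp@train, fps, latentDim = 6, nSamples = 40, burnIn = 30,
                     seed = 1)
      pred <- predictActivity(trc, fpsTe)
      heldOutRmsd(pred, activityValues(sp@test), observedMask(sp@test))
    }
    withr::with_seed(s, {
      shufBits <- fingerprintBits(fpsTr)[sample(nrow(fingerprintBits(fpsTr))), ]
      rownames(shufBits) <- compoundIds(sp@train)
      rmsdOf(fpsTr) - rmsdOf(FingerprintSet(shufBits))
    })
  }, numeric(1))
  expect_lt(stats::median(rmsds), 0)
})
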