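test_that("maskedLoss matches hand-computed values and ignores unobserved cells", {
  v <- matrix(c(1, 2, NA, 4), 2, 2, dimnames = list(c("c1", "c2"), c("a1", "a2")))
  am <- ActivityMatrix(v)
  p <- matrix(c(1, 2, 99, 4), 2, 2)
  expect_equal(maskedLoss(p, am), 0)                      # perfect on observed
  p2 <- p; p2[2, 2] <- 6                                  # one residual of 2
  expect_equal(maskedLoss(p2, am), 4 / 3)                 # mean over 3 observed
  p3 <- p2; p3[1, 2] <- -1e6                              # unobserved cell
  expect_equal(maskedLoss(p3, am), maskedLoss(p2, am))

  allMiss <- ActivityMatrix(matrix(NA_real_, 2, 2,
    dimnames = list(c("c1", "c2"), c("a1", "a2"))))
  expect_equal(maskedLoss(p, allMiss), 0)                 # empty mask -> 0
  expect_error(maskedLoss(matrix(0, 3, 2), am), "aligned")
})

test_that("classification maskedLoss is the mean binary cross-entropy over observed cells", {
  v <- matrix(c(1, 0, NA, 1), 2, 2, dimnames = list(c("c1", "c2"), c("a1", "a2")))
  am <- ActivityMatrix(v, taskType = "classification")
  p <- matrix(c(0.9, 0.2, 0.5, 0.7), 2, 2)
  hand <- -mean(c(log(0.9), log(1 - 0.2), log(0.7)))
  expect_equal(maskedLoss(p, am), hand)
})

test_that("analytic gradients match central finite differences for both task types", {
  set.seed(4)
  X <- matrix(rbinom(5 * 6, 1, 0.4), 5, 6)
  storage.mode(X) <- "double"
  mask <- matrix(rbinom(5 * 3, 1, 0.7), 5, 3) * 1
  grad <- multitaskSparsity:::nnLossGrad
  lossAt <- function(params, Y, tt) grad(params, X, Y, mask, "relu", tt)$loss
  for (tt in c("regression", "classification")) {
    Y <- if (tt == "regression") matrix(rnorm(15), 5, 3) else
      matrix(rbinom(15, 1, 0.5), 5, 3) * 1
    params <- multitaskSparsity:::nnInitParams(c(6, 4, 3))
    g <- grad(params, X, Y, mask, "relu", tt)
    h <- 1e-6
    for (l in 1:2) {
      for (k in sample(length(params$weights[[l]]), 6)) {
        up <- params; up$weights[[l]][k] <- up$weights[[l]][k] + h
        dn <- params; dn$weights[[l]][k] <- dn$weights[[l]][k] - h
        fd <- (lossAt(up, Y, tt) - lossAt(dn, Y, tt)) / (2 * h)
        expect_equal(g$gW[[l]][k], fd, tolerance = 1e-4)
      }
      for (k in seq_along(params$biases[[l]])) {
        up <- params; up$biases[[l]][k] <- up$biases[[l]][k] + h
        dn <- params; dn$biases[[l]][k] <- dn$biases[[l]][k] - h
        fd <- (lossAt(up, Y, tt) - lossAt(dn, Y, tt)) / (2 * h)
        expect_equal(g$gB[[l]][k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("an all-false mask yields zero loss and exactly zero gradients", {
  set.seed(7)
  X <- matrix(rbinom(12, 1, 0.5), 4, 3) * 1
  Y <- matrix(rnorm(8), 4, 2)
  params <- multitaskSparsity:::nnInitParams(c(3, 2, 2))
  g <- multitaskSparsity:::nnLossGrad(params, X, Y, matrix(0, 4, 2),
                                      "relu", "regression")
  expect_equal(g$loss, 0)
  expect_true(all(vapply(g$gW, function(w) all(w == 0), logical(1))))
  expect_true(all(vapply(g$gB, function(b) all(b == 0), logical(1))))
})

test_that("a linear single-unit network converges to the least-squares solution", {
  set.seed(9)
  n <- 20
  bits <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
                 dimnames = list(sprintf("c%02d", 1:n), NULL))
  bits[bits[, 1] + bits[, 2] == 0, 1] <- 1   # no all-zero fingerprint rows
  storage.mode(bits) <- "integer"
  y <- 3 * bits[, 1] - 2 * bits[, 2] + 1
  am <- ActivityMatrix(matrix(y, n, 1, dimnames = list(rownames(bits), "a1")))
  fps <- FingerprintSet(bits)
  net <- nnFit(am, fps, hiddenSizes = 1L, activation = "linear",
               trainSteps = 8000L, minibatch = 20L, seed = 2)
  ls <- stats::lm.fit(cbind(1, bits), y)
  lsPred <- cbind(1, bits) %*% ls$coefficients
  expect_lt(max(abs(predictActivityNet(net, fps) - lsPred)), 1e-3)
})

test_that("training and inference are deterministic given the seed", {
  dat <- smallDataset(n = 30, m = 4, seed = 5)
  a <- nnFit(dat$activity, dat$fingerprints, trainSteps = 50L, seed = 3)
  b <- nnFit(dat$activity, dat$fingerprints, trainSteps = 50L, seed = 3)
  expect_identical(a@weights, b@weights)
  expect_identical(predictActivityNet(a, dat$fingerprints),
                   predictActivityNet(b, dat$fingerprints))
  c_ <- nnFit(dat$activity, dat$fingerprints, trainSteps = 50L, seed = 4)
  expect_false(identical(a@weights, c_@weights))
})

test_that("finalLoss is reproduced by scoring the network's own predictions", {
  dat <- smallDataset(n = 25, m = 3, seed = 6)
  tr <- removeLabels(dat$activity, 0.2, seed = 1)
  net <- nnFit(tr, dat$fingerprints, trainSteps = 200L, dropout = 0.2, seed = 5)
  expect_equal(maskedLoss(predictActivityNet(net, dat$fingerprints), tr),
               net@finalLoss)
})

test_that("noiseless fingerprint-driven data trains to small error", {
  cfg <- syntheticConfig(nCompounds = 120, nAssays = 4, latentRank = 2L,
                         assayClusters = 2L, noiseSd = 0,
                         signalFromFingerprint = 1, nBits = 64L,
                         bitsSetRange = c(8L, 16L, 24L),
                         missingFraction = 0, seed = 3)
  out <- genRegressionMatrix(cfg)
  net <- nnFit(out$activity, out$fingerprints, hiddenSizes = 32L,
               trainSteps = 3000L, seed = 1)
  pred <- predictActivityNet(net, out$fingerprints)
  vals <- activityValues(out$activity)
  rmsd <- sqrt(mean((pred - vals)^2))
  expect_lt(rmsd, 0.10 * diff(range(vals)))
})

test_that("classification nets emit probabilities and 0.5-ties go active", {
  dat <- smallDataset(n = 25, m = 3, seed = 7, taskType = "classification")
  net <- nnFit(dat$activity, dat$fingerprints, trainSteps = 100L, seed = 2)
  pr <- predictActivityNet(net, dat$fingerprints)
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predictActivityNet(net, dat$fingerprints, type = "class")
  expect_true(all(cl %in% c(0, 1)))
  expect_identical(cl, (pr >= 0.5) * 1, ignore_attr = TRUE)
})

test_that("misaligned or mis-sized fingerprints are rejected", {
  dat <- smallDataset(n = 10, m = 3, seed = 8)
  net <- nnFit(dat$activity, dat$fingerprints, trainSteps = 10L, seed = 1)
  wide <- FingerprintSet(cbind(fingerprintBits(dat$fingerprints), extra = 1L))
  expect_error(predictActivityNet(net, wide), "width")
  v <- activityValues(dat$activity)
  v[, 2] <- NA
  expect_error(nnFit(ActivityMatrix(v), dat$fingerprints, trainSteps = 5L),
               "without any training label")
})
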