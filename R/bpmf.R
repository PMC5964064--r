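#' @include data_core.R
NULL

# --- Normal-Wishart conditional for latent-matrix hyperparameters ----------
# Residuals R (rows ~ N(mu, Lambda^-1)); weakly informative hyperprior
# mu0 = 0, kappa0 = 1, nu0 = k, W0 = I.
sampleNormalWishart <- function(R) {
  n <- nrow(R); k <- ncol(R)
  mu0 <- rep(0, k); kappa0 <- 1; nu0 <- k; W0inv <- diag(k)
  rbar <- colMeans(R)
  Sc <- crossprod(sweep(R, 2L, rbar))            # n * sample covariance
  kappaN <- kappa0 + n
  nuN <- nu0 + n
  muN <- (kappa0 * mu0 + n * rbar) / kappaN
  d <- rbar - mu0
  WNinv <- W0inv + Sc + (kappa0 * n / kappaN) * tcrossprod(d)
  WN <- chol2inv(chol((WNinv + t(WNinv)) / 2))
  Lambda <- stats::rWishart(1L, nuN, WN)[, , 1L]
  Lambda <- (Lambda + t(Lambda)) / 2
  Ru <- chol(Lambda)
  mu <- muN + backsolve(Ru, stats::rnorm(k)) / sqrt(kappaN)
  list(mu = mu, Lambda = Lambda, cholLambda = Ru)
}

# Sample one latent row from N(P^-1 b, P^-1); errors carry the sweep index.
sampleGaussianCanonical <- function(P, b, sweepIdx) {
  Rp <- tryCatch(chol(P), error = function(e)
    stopfmt("non-positive-definite conditional precision at sweep %d", sweepIdx))
  mu <- backsolve(Rp, backsolve(Rp, b, transpose = TRUE))
  mu + backsolve(Rp, stats::rnorm(length(b)))
}

#' Regularized matrix-factorization objective
#'
#' The frequentist view of the factorization: squared reconstruction error
#' over observed cells plus Frobenius penalties,
#' `sum_(i,j in observed) (X_ij - u_i v_j')^2 + lambdaU ||U||_F^2 +
#' lambdaV ||V||_F^2`, evaluated on centered values. Used as a convergence
#' diagnostic for the sampler's running posterior mean.
#'
#' @param train an [ActivityMatrix-class].
#' @param U,V latent matrices (n x k, m x k).
#' @param lambdaU,lambdaV Frobenius regularization weights.
#' @param center value subtracted from observed entries before the residual
#'   (default: their mean).
#' @return the scalar objective.
#' @export
mapObjective <- function(train, U, V, lambdaU = 1, lambdaV = 1,
                         center = NULL) {
  stopifnot(is(train, "ActivityMatrix"))
  obs <- train@observed
  if (is.null(center)) center <- mean(train@values[obs])
  if (nrow(U) != nrow(obs) || nrow(V) != ncol(obs) || ncol(U) != ncol(V))
    stopfmt("latent dimensions do not match the activity matrix")
  recon <- U %*% t(V)
  resid <- (train@values - center) - recon
  sum(resid[obs]^2) + lambdaU * sum(U^2) + lambdaV * sum(V^2)
}

#' Fit Bayesian probabilistic matrix factorization with fingerprint side
#' information
#'
#' Gibbs sampler for the low-rank model `X ~ U V'` with Gaussian priors on
#' the latent vectors, Normal-Wishart hyperpriors on their means and
#' precisions, and compound fingerprints folded into the prior mean of the
#' compound latents through a link matrix beta (the Macau construction):
#' `u_i ~ N(mu_u + beta' f_i, Lambda_u^-1)`. Assays carry no side
#' information. Each sweep (1) samples beta from its matrix-normal ridge
#' conditional, (2) samples the Normal-Wishart hyperparameters on both sides
#' (the compound side centered on the residuals `U - F beta`), (3) samples
#' every compound latent from its Gaussian conditional with precision
#' `Lambda_u + alpha * sum_j v_j v_j'` over that compound's observed cells,
#' and (4) symmetrically every assay latent. Post burn-in snapshots form the
#' trace; predictions average over them.
#'
#' Observed values are standardized (centered and scaled by their standard
#' deviation) before factorization and the transform undone at prediction,
#' so the fixed noise precision refers to a unit-variance response.
#'
#' @param train training [ActivityMatrix-class] (regression values or 0/1
#'   labels; classification is regression-on-labels with rounding at
#'   prediction, see [predictClass()]).
#' @param fps [FingerprintSet-class] row-aligned with `train`.
#' @param latentDim latent space size k.
#' @param nSamples post burn-in Gibbs sweeps kept in the trace.
#' @param burnIn discarded initial sweeps.
#' @param noisePrecision alpha, observation precision on the standardized
#'   scale (fixed, not sampled).
#' @param linkPrecision lambda_beta, ridge precision of the link matrix.
#' @param seed integer seed; the trace is reproducible given the seed.
#' @param emptyAction `"error"` (default) stops when any assay or compound
#'   has no observed training label, naming it; `"prune"` drops such rows and
#'   columns and fits on the remainder.
#' @return a [BPMFTrace-class].
#' @examples
#' dat <- genRegressionMatrix(syntheticConfig(nCompounds = 30, nAssays = 6,
#'                                            nBits = 128, seed = 3))
#' tr <- bpmfFit(dat$activity, dat$fingerprints, latentDim = 3,
#'               nSamples = 20, burnIn = 10, seed = 1)
#' pred <- predictActivity(tr, dat$fingerprints)
#' @export
bpmfFit <- function(train, fps, latentDim = 8L, nSamples = 100L,
                    burnIn = 50L, noisePrecision = 5, linkPrecision = 5,
                    seed = 1L, emptyAction = c("error", "prune")) {
  stopifnot(is(train, "ActivityMatrix"), is(fps, "FingerprintSet"))
  emptyAction <- match.arg(emptyAction)
  if (latentDim < 1L || nSamples < 1L || burnIn < 0L)
    stopfmt("latentDim >= 1, nSamples >= 1, burnIn >= 0 required")
  if (noisePrecision <= 0 || linkPrecision <= 0)
    stopfmt("precisions must be > 0")
  if (!identical(rownames(train@values), rownames(fps@bits)))
    stopfmt("fingerprints are not aligned with the training matrix")
  empt <- auditEmpty(train)
  if (length(empt$emptyAssays) || length(empt$emptyCompounds)) {
    if (emptyAction == "error") {
      what <- c(if (length(empt$emptyAssays))
                  sprintf("assays without labels: %s",
                          paste(utils::head(empt$emptyAssays, 5), collapse = ", ")),
                if (length(empt$emptyCompounds))
                  sprintf("compounds without labels: %s",
                          paste(utils::head(empt$emptyCompounds, 5), collapse = ", ")))
      stopfmt("cannot fit on training data with empty slices (%s)",
              paste(what, collapse = "; "))
    }
    keepI <- rowSums(train@observed) > 0L
    keepJ <- colSums(train@observed) > 0L
    train <- subsetActivity(train, i = which(keepI), j = which(keepJ))
    fps <- FingerprintSet(fps@bits[keepI, , drop = FALSE])
  }

  k <- as.integer(latentDim)
  alpha <- noisePrecision
  X <- train@values
  obs <- train@observed
  n <- nrow(X); m <- ncol(X)
  obsVals <- X[obs]
  center <- mean(obsVals)
  scaleFactor <- stats::sd(obsVals)
  if (!is.finite(scaleFactor) || scaleFactor == 0) scaleFactor <- 1
  Xs <- (X - center) / scaleFactor
  Xs[!obs] <- 0

  FPB <- fps@bits
  storage.mode(FPB) <- "double"
  B <- ncol(FPB)
  obsByRow <- lapply(seq_len(n), function(i) which(obs[i, ]))
  obsByCol <- lapply(seq_len(m), function(j) which(obs[, j]))

  # ridge precision of the link conditional is sweep-invariant
  K <- crossprod(FPB) + diag(linkPrecision, B)
  cholK <- chol(K)

  # standardized copy for the convergence diagnostic (numeric view only)
  valsStd <- Xs
  valsStd[!obs] <- NA_real_
  trainStd <- new("ActivityMatrix", values = valsStd, observed = obs,
                  taskType = "regression")

  withSeed(seed, {
    U <- matrix(0, n, k, dimnames = list(rownames(X), NULL))
    V <- matrix(0, m, k); beta <- matrix(0, B, k)
    samples <- vector("list", nSamples)
    objective <- numeric(nSamples)
    runU <- matrix(0, n, k); runV <- matrix(0, m, k)
    total <- burnIn + nSamples
    for (sw in seq_len(total)) {
      # (1) link matrix: matrix-normal conditional of the ridge regression of
      # the compound latents on fingerprint bits (column covariance tied to
      # Lambda_u so the row precision K is free of it)
      huPrev <- if (sw == 1L) {
        list(mu = rep(0, k), Lambda = diag(k), cholLambda = diag(k))
      } else hu
      Umu <- sweep(U, 2L, huPrev$mu)
      M <- backsolve(cholK, backsolve(cholK, crossprod(FPB, Umu),
                                      transpose = TRUE))
      Z <- matrix(stats::rnorm(B * k), B, k)
      W <- t(backsolve(huPrev$cholLambda, t(Z)))
      beta <- M + backsolve(cholK, W)
      Fb <- FPB %*% beta

      # (2) hyperparameters
      hu <- sampleNormalWishart(U - Fb)
      hv <- sampleNormalWishart(V)

      # (3) compound latents
      priorMeanU <- sweep(Fb, 2L, hu$mu, "+")
      LmuU <- hu$Lambda
      for (i in seq_len(n)) {
        jj <- obsByRow[[i]]
        Vs <- V[jj, , drop = FALSE]
        P <- LmuU + alpha * crossprod(Vs)
        b <- LmuU %*% priorMeanU[i, ] + alpha * crossprod(Vs, Xs[i, jj])
        U[i, ] <- sampleGaussianCanonical(P, b, sw)
      }

      # (4) assay latents (prior mean mu_v only; no side information)
      LmuV <- hv$Lambda
      bv0 <- LmuV %*% hv$mu
      for (j in seq_len(m)) {
        ii <- obsByCol[[j]]
        Us <- U[ii, , drop = FALSE]
        P <- LmuV + alpha * crossprod(Us)
        b <- bv0 + alpha * crossprod(Us, Xs[ii, j])
        V[j, ] <- sampleGaussianCanonical(P, b, sw)
      }

      if (sw > burnIn) {
        s <- sw - burnIn
        samples[[s]] <- list(U = U, V = V, beta = beta, muU = hu$mu)
        runU <- runU + (U - runU) / s
        runV <- runV + (V - runV) / s
        objective[s] <- mapObjective(trainStd, runU, runV, center = 0)
      }
    }
    trace <- new("BPMFTrace", samples = samples, center = center,
                 scaleFactor = scaleFactor,
                 assayIds = colnames(X), taskType = train@taskType,
                 config = list(latentDim = k, nSamples = as.integer(nSamples),
                               burnIn = as.integer(burnIn),
                               noisePrecision = alpha,
                               linkPrecision = linkPrecision,
                               seed = as.integer(seed),
                               trainCompoundIds = rownames(X),
                               objective = objective))
    trace
  })
}

setMethod("show", "BPMFTrace", function(object) {
  cfg <- object@config
  cat(sprintf("BPMFTrace: %d samples (burn-in %d), k = %d, %d assays, %s task\n",
              length(object@samples), cfg$burnIn, cfg$latentDim,
              length(object@assayIds), object@taskType))
})

#' Posterior-mean predictions from a fitted trace
#'
#' For compounds seen in training, each snapshot reconstructs `u_i v_j'`; for
#' unseen (cold-start) compounds the latent is the prior mean
#' `mu_u + beta' f` of that snapshot. The final prediction is the mean over
#' snapshots, mapped back to response units.
#'
#' @param trace a [BPMFTrace-class].
#' @param fps [FingerprintSet-class] for the compounds to predict (seen or
#'   unseen).
#' @param assays optional character vector of assay ids (default: all assays
#'   of the trace); unknown ids raise an error.
#' @param se if `TRUE`, also return the per-cell standard deviation across
#'   snapshots.
#' @return numeric matrix compounds x assays (list with `mean` and `sd` when
#'   `se = TRUE`).
#' @export
predictActivity <- function(trace, fps, assays = NULL, se = FALSE) {
  stopifnot(is(trace, "BPMFTrace"), is(fps, "FingerprintSet"))
  if (is.null(assays)) assays <- trace@assayIds
  unknown <- setdiff(assays, trace@assayIds)
  if (length(unknown))
    stopfmt("unknown assay id(s): %s", paste(utils::head(unknown, 5), collapse = ", "))
  jIdx <- match(assays, trace@assayIds)
  ids <- rownames(fps@bits)
  trainIds <- trace@config$trainCompoundIds
  seen <- match(ids, trainIds)
  FPB <- fps@bits
  storage.mode(FPB) <- "double"
  acc <- 0; acc2 <- 0
  for (s in trace@samples) {
    Unew <- matrix(0, length(ids), trace@config$latentDim)
    isSeen <- !is.na(seen)
    if (any(isSeen)) Unew[isSeen, ] <- s$U[seen[isSeen], , drop = FALSE]
    if (any(!isSeen)) {
      cold <- FPB[!isSeen, , drop = FALSE] %*% s$beta
      Unew[!isSeen, ] <- sweep(cold, 2L, s$muU, "+")
    }
    rec <- Unew %*% t(s$V[jIdx, , drop = FALSE])
    acc <- acc + rec
    if (se) acc2 <- acc2 + rec^2
  }
  nS <- length(trace@samples)
  meanStd <- acc / nS
  pred <- meanStd * trace@scaleFactor + trace@center
  dimnames(pred) <- list(ids, assays)
  if (!se) return(pred)
  varStd <- pmax(acc2 / nS - meanStd^2, 0)
  sd <- sqrt(varStd) * trace@scaleFactor
  dimnames(sd) <- dimnames(pred)
  list(mean = pred, sd = sd)
}

#' @describeIn predictActivity `predict` method for `BPMFTrace`.
#' @param object a [BPMFTrace-class].
#' @param ... passed on to `predictActivity`.
#' @export
setMethod("predict", "BPMFTrace", function(object, ...) {
  predictActivity(object, ...)
})

#' Round factorization predictions to class labels
#'
#' The factorization is a regression technique; for classification tasks its
#' predictions are rounded to the nearest integer and clamped to \{0, 1\}.
#' A prediction of exactly 0.5 rounds to 1 (active).
#'
#' @param predictions numeric matrix or vector of predicted values.
#' @return 0/1 labels with the same shape.
#' @export
roundToClass <- function(predictions) {
  lab <- roundHalfUp(predictions)
  lab[lab < 0] <- 0
  lab[lab > 1] <- 1
  lab
}

#' @rdname roundToClass
#' @param trace a [BPMFTrace-class] fitted on a classification matrix.
#' @param fps fingerprints of the compounds to predict.
#' @param assays optional assay subset.
#' @export
predictClass <- function(trace, fps, assays = NULL) {
  roundToClass(predictActivity(trace, fps, assays = assays))
}
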