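#' @include data_core.R
NULL

#' Masked multitask loss
#'
#' Training loss of the multitask network: only observed cells contribute.
#' Regression uses the mean squared error over observed cells; classification
#' uses the mean binary cross-entropy of predicted probabilities over
#' observed cells. A prediction grid whose mask is all-false contributes 0,
#' and changing predictions at unobserved cells never changes the loss.
#'
#' @param predictions numeric matrix aligned with the activity matrix
#'   (response values for regression, probabilities in (0, 1) for
#'   classification).
#' @param x an [ActivityMatrix-class].
#' @return the scalar loss.
#' @export
maskedLoss <- function(predictions, x) {
  stopifnot(is(x, "ActivityMatrix"))
  predictions <- as.matrix(predictions)
  if (!identical(dim(predictions), dim(x@values)))
    stopfmt("predictions are not aligned with the activity matrix")
  obs <- x@observed
  if (!any(obs)) return(0)
  y <- x@values[obs]
  p <- predictions[obs]
  if (x@taskType == "regression") {
    mean((y - p)^2)
  } else {
    eps <- 1e-12
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

# fan-in scaled uniform initialization
nnInitParams <- function(sizes) {
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / sizes[l])
    weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                           sizes[l], sizes[l + 1L])
    biases[[l]] <- rep(0, sizes[l + 1L])
  }
  list(weights = weights, biases = biases)
}

# Forward pass. dropMasks: NULL at inference, list of inverted-dropout masks
# (per hidden layer) during training. Returns activations per layer and the
# output (pre-link for regression, probability for classification).
nnForward <- function(params, X, activation, taskType, dropMasks = NULL) {
  L <- length(params$weights)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% params$weights[[l]], 2L, params$biases[[l]], "+")
    if (l < L) {
      A <- if (activation == "relu") pmax(Z, 0) else Z
      if (!is.null(dropMasks) && !is.null(dropMasks[[l]])) A <- A * dropMasks[[l]]
      acts[[l + 1L]] <- A
    } else {
      acts[[l + 1L]] <- if (taskType == "classification") 1 / (1 + exp(-Z)) else Z
    }
  }
  acts
}

# Masked loss + analytic gradients for one batch. For regression the loss is
# mean squared error over observed cells; for classification mean binary
# cross-entropy on sigmoid outputs. Both yield dL/dZ_out =
# scale * (pred - y) * mask with scale = 2/nObs (MSE) or 1/nObs (BCE).
nnLossGrad <- function(params, X, Y, mask, activation, taskType,
                       dropMasks = NULL) {
  acts <- nnForward(params, X, activation, taskType, dropMasks)
  L <- length(params$weights)
  out <- acts[[L + 1L]]
  nObs <- sum(mask)
  gW <- lapply(params$weights, function(w) w * 0)
  gB <- lapply(params$biases, function(b) b * 0)
  if (nObs == 0)
    return(list(loss = 0, gW = gW, gB = gB))
  resid <- (out - Y) * mask
  if (taskType == "regression") {
    loss <- sum(resid[mask > 0]^2) / nObs
    delta <- 2 * resid / nObs
  } else {
    eps <- 1e-12
    p <- pmin(pmax(out, eps), 1 - eps)
    loss <- -sum((Y * log(p) + (1 - Y) * log(1 - p))[mask > 0]) / nObs
    delta <- resid / nObs   # sigmoid + BCE: dL/dZ = (p - y)/nObs
  }
  for (l in seq(L, 1L)) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gB[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params$weights[[l]])
      if (activation == "relu") delta <- delta * (acts[[l]] > 0)
      if (!is.null(dropMasks) && !is.null(dropMasks[[l - 1L]]))
        delta <- delta * dropMasks[[l - 1L]]
    }
  }
  list(loss = loss, gW = gW, gB = gB)
}

#' Fit a fully connected multitask network with a masked loss
#'
#' Fingerprint-in / activity-profile-out feed-forward network: 1024-bit (or
#' configured-width) fingerprints enter, one output unit per assay leaves
#' (linear outputs for regression, sigmoid for classification). Hidden units
#' use ReLU (a linear option exists for degeneracy checks). Unobserved cells
#' contribute nothing to the loss or its gradients, so matrices sparsified by
#' label removal train directly. Optimized by Adagrad (default learning rate
#' 0.05) on minibatches of compounds, each carrying all of that compound's
#' observed labels. Regression responses are standardized internally and the
#' transform undone at prediction.
#'
#' @param train training [ActivityMatrix-class].
#' @param fps row-aligned [FingerprintSet-class].
#' @param hiddenSizes integer vector, one entry per hidden layer.
#' @param dropout hidden-unit dropout probability in \[0, 1) (inverted
#'   dropout; disabled at inference).
#' @param trainSteps number of minibatch gradient steps.
#' @param minibatch compounds per minibatch.
#' @param learningRate Adagrad learning rate.
#' @param activation hidden activation, `"relu"` (default) or `"linear"`.
#' @param seed integer seed (initialization, minibatch order, dropout).
#' @param emptyAction `"error"` (default) or `"prune"` for assays with no
#'   observed training label.
#' @return a [MultitaskNet-class]; its `finalLoss` slot holds the masked loss
#'   of the final model over the full training matrix on the response scale,
#'   reproducible by feeding `predict()` output to [maskedLoss()].
#' @export
nnFit <- function(train, fps, hiddenSizes = c(64L), dropout = 0,
                  trainSteps = 2000L, minibatch = 32L, learningRate = 0.05,
                  activation = c("relu", "linear"), seed = 1L,
                  emptyAction = c("error", "prune")) {
  stopifnot(is(train, "ActivityMatrix"), is(fps, "FingerprintSet"))
  activation <- match.arg(activation)
  emptyAction <- match.arg(emptyAction)
  if (length(hiddenSizes) < 1L || any(hiddenSizes < 1L))
    stopfmt("need at least one hidden layer of >= 1 unit")
  if (minibatch < 1L) stopfmt("minibatch must be >= 1")
  if (dropout < 0 || dropout >= 1) stopfmt("dropout must be in [0, 1)")
  if (!identical(rownames(train@values), rownames(fps@bits)))
    stopfmt("fingerprints are not aligned with the training matrix")
  empt <- auditEmpty(train)
  if (length(empt$emptyAssays)) {
    if (emptyAction == "error")
      stopfmt("assays without any training label: %s",
              paste(utils::head(empt$emptyAssays, 5), collapse = ", "))
    keepJ <- colSums(train@observed) > 0L
    train <- subsetActivity(train, j = which(keepJ))
  }
  X <- fps@bits
  storage.mode(X) <- "double"
  n <- nrow(X); m <- ncol(train@values)
  obs <- train@observed
  Y <- train@values
  if (train@taskType == "regression") {
    yObs <- Y[obs]
    center <- mean(yObs)
    scaleFactor <- stats::sd(yObs)
    if (!is.finite(scaleFactor) || scaleFactor == 0) scaleFactor <- 1
    Y <- (Y - center) / scaleFactor
  } else {
    center <- 0; scaleFactor <- 1
  }
  Y[!obs] <- 0
  mask <- matrix(as.numeric(obs), n, m)

  sizes <- c(ncol(X), as.integer(hiddenSizes), m)
  withSeed(seed, {
    params <- nnInitParams(sizes)
    accW <- lapply(params$weights, function(w) w * 0)
    accB <- lapply(params$biases, function(b) b * 0)
    epsAda <- 1e-8
    nHidden <- length(hiddenSizes)
    for (step in seq_len(trainSteps)) {
      idx <- sample.int(n, min(minibatch, n))
      dropMasks <- NULL
      if (dropout > 0) {
        dropMasks <- lapply(seq_len(nHidden), function(l) {
          matrix(stats::rbinom(length(idx) * sizes[l + 1L], 1L, 1 - dropout),
                 length(idx), sizes[l + 1L]) / (1 - dropout)
        })
      }
      g <- nnLossGrad(params, X[idx, , drop = FALSE],
                      Y[idx, , drop = FALSE], mask[idx, , drop = FALSE],
                      activation, train@taskType, dropMasks)
      for (l in seq_along(params$weights)) {
        accW[[l]] <- accW[[l]] + g$gW[[l]]^2
        accB[[l]] <- accB[[l]] + g$gB[[l]]^2
        params$weights[[l]] <- params$weights[[l]] -
          learningRate * g$gW[[l]] / sqrt(accW[[l]] + epsAda)
        params$biases[[l]] <- params$biases[[l]] -
          learningRate * g$gB[[l]] / sqrt(accB[[l]] + epsAda)
      }
    }
    net <- new("MultitaskNet", weights = params$weights,
               biases = params$biases, activation = activation,
               taskType = train@taskType, assayIds = colnames(train@values),
               center = center, scaleFactor = scaleFactor,
               finalLoss = NA_real_,
               config = list(hiddenSizes = as.integer(hiddenSizes),
                             dropout = dropout,
                             trainSteps = as.integer(trainSteps),
                             minibatch = as.integer(minibatch),
                             learningRate = learningRate, seed = as.integer(seed)))
    net@finalLoss <- maskedLoss(predictActivityNet(net, fps), train)
    net
  })
}

setMethod("show", "MultitaskNet", function(object) {
  cat(sprintf("MultitaskNet (%s, %s): %s -> %s -> %d assays; final masked loss %.4g\n",
              object@taskType, object@activation,
              nrow(object@weights[[1L]]),
              paste(object@config$hiddenSizes, collapse = "-"),
              length(object@assayIds), object@finalLoss))
})

#' Network predictions
#'
#' Deterministic inference pass (dropout disabled). Regression predictions
#' are returned on the response scale; classification predictions as
#' probabilities, or as 0/1 labels thresholded at 0.5 (0.5 itself maps to
#' active, consistent with the factorization's rounding rule) when
#' `type = "class"`.
#'
#' @param net a [MultitaskNet-class].
#' @param fps [FingerprintSet-class] of compounds to predict; bit width must
#'   match the training fingerprints.
#' @param type `"response"` (default) or `"class"` (classification only).
#' @return numeric matrix compounds x assays.
#' @export
predictActivityNet <- function(net, fps, type = c("response", "class")) {
  stopifnot(is(net, "MultitaskNet"), is(fps, "FingerprintSet"))
  type <- match.arg(type)
  X <- fps@bits
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(net@weights[[1L]]))
    stopfmt("fingerprint width %d does not match the network input width %d",
            ncol(X), nrow(net@weights[[1L]]))
  acts <- nnForward(list(weights = net@weights, biases = net@biases), X,
                    net@activation, net@taskType)
  out <- acts[[length(acts)]]
  if (net@taskType == "regression") out <- out * net@scaleFactor + net@center
  dimnames(out) <- list(rownames(X), net@assayIds)
  if (type == "class") {
    if (net@taskType != "classification")
      stopfmt("type = 'class' requires a classification network")
    out <- (out >= 0.5) * 1
  }
  out
}

#' @describeIn predictActivityNet `predict` method for `MultitaskNet`.
#' @param object a [MultitaskNet-class].
#' @param ... passed on to `predictActivityNet`.
#' @export
setMethod("predict", "MultitaskNet", function(object, ...) {
  predictActivityNet(object, ...)
})
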