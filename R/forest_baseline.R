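#' @include data_core.R
NULL

#' Impute pre-existing missing cells with the assay mean
#'
#' Replaces every unobserved cell by the mean of its assay's observed values
#' and marks the whole matrix observed. Intended for the handful of missing
#' cells a curated panel carries before any sparsification; it is the only
#' gap-filling the tree-ensemble baseline receives. Idempotent.
#'
#' @param x an [ActivityMatrix-class]; every assay needs >= 1 observed value.
#' @return a fully observed [ActivityMatrix-class].
#' @export
imputeAssayMean <- function(x) {
  stopifnot(is(x, "ActivityMatrix"))
  if (all(x@observed)) return(x)
  nObsCol <- colSums(x@observed)
  if (any(nObsCol == 0L))
    stopfmt("assay(s) with no observed value cannot be mean-imputed: %s",
            paste(utils::head(colnames(x@values)[nObsCol == 0L], 5), collapse = ", "))
  vals <- x@values
  colMeansObs <- colSums(ifelse(x@observed, vals, 0)) / nObsCol
  miss <- which(!x@observed, arr.ind = TRUE)
  vals[miss] <- colMeansObs[miss[, 2L]]
  if (x@taskType == "classification") vals[miss] <- roundHalfUp(vals[miss])
  new("ActivityMatrix", values = vals,
      observed = matrix(TRUE, nrow(vals), ncol(vals), dimnames = dimnames(vals)),
      taskType = x@taskType)
}

#' Fit the per-assay random-forest baseline
#'
#' One tree ensemble per assay over fingerprint bits (trees are delegated to
#' \pkg{ranger}; the multi-output behavior lives behind this surface).
#' Regression ensembles combine trees by the mean; classification by vote
#' fraction with ties resolved to active. The learner requires a complete
#' training matrix: label- or assay-removed (sparse) matrices are rejected
#' with an error, mirroring tree-ensemble implementations that cannot train
#' with missing outputs — use it with the compound removal model only (after
#' [imputeAssayMean()] for pre-existing gaps).
#'
#' @param train fully observed [ActivityMatrix-class].
#' @param fps row-aligned [FingerprintSet-class].
#' @param nTrees trees per assay ensemble.
#' @param maxFeatures number (if > 1) or fraction (if <= 1) of fingerprint
#'   bits tried at each split; `NULL` for the learner default (sqrt of the
#'   bit count).
#' @param bootstrap draw a bootstrap sample per tree (`TRUE`) or grow every
#'   tree on the full training set (`FALSE`).
#' @param seed integer seed.
#' @return a [ForestModel-class].
#' @export
forestFit <- function(train, fps, nTrees = 100L, maxFeatures = NULL,
                      bootstrap = TRUE, seed = 1L) {
  stopifnot(is(train, "ActivityMatrix"), is(fps, "FingerprintSet"))
  if (nTrees < 1L) stopfmt("nTrees must be >= 1")
  if (!all(train@observed))
    stopfmt(paste("the tree-ensemble baseline requires a complete training",
                  "matrix; it can only be used with the compound removal model",
                  "(impute pre-existing gaps with imputeAssayMean())"))
  if (!identical(rownames(train@values), rownames(fps@bits)))
    stopfmt("fingerprints are not aligned with the training matrix")
  X <- as.data.frame(fps@bits)
  mtry <- if (is.null(maxFeatures)) NULL
          else if (maxFeatures > 1) as.integer(maxFeatures)
          else max(1L, as.integer(round(maxFeatures * ncol(X))))
  m <- ncol(train@values)
  forests <- vector("list", m)
  for (j in seq_len(m)) {
    yj <- train@values[, j]
    if (train@taskType == "classification") yj <- factor(yj, levels = c(0, 1))
    forests[[j]] <- ranger::ranger(
      x = X, y = yj, num.trees = nTrees, mtry = mtry,
      replace = bootstrap, sample.fraction = 1,
      min.node.size = 1L,
      probability = train@taskType == "classification",
      num.threads = 1L, seed = deriveSeed(seed, j))
  }
  new("ForestModel", forests = forests, taskType = train@taskType,
      assayIds = colnames(train@values),
      config = list(nTrees = as.integer(nTrees), maxFeatures = maxFeatures,
                    bootstrap = bootstrap, seed = as.integer(seed)))
}

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel (%s): %d assays x %d trees (bootstrap %s)\n",
              object@taskType, length(object@forests),
              object@config$nTrees, object@config$bootstrap))
})

#' Forest predictions
#'
#' @param model a [ForestModel-class].
#' @param fps [FingerprintSet-class] of compounds to predict.
#' @param type `"response"` (regression values / active-vote fraction) or
#'   `"class"` (0/1 labels, vote fraction >= 0.5 meaning active).
#' @return numeric matrix compounds x assays.
#' @export
predictActivityForest <- function(model, fps, type = c("response", "class")) {
  stopifnot(is(model, "ForestModel"), is(fps, "FingerprintSet"))
  type <- match.arg(type)
  X <- as.data.frame(fps@bits)
  preds <- vapply(model@forests, function(fo) {
    p <- stats::predict(fo, data = X, num.threads = 1L)$predictions
    if (is.matrix(p)) p[, "1"] else p
  }, numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X),
                  dimnames = list(rownames(fps@bits), model@assayIds))
  if (type == "class") {
    if (model@taskType != "classification")
      stopfmt("type = 'class' requires a classification model")
    preds <- (preds >= 0.5) * 1
  }
  preds
}

#' @describeIn predictActivityForest `predict` method for `ForestModel`.
#' @param object a [ForestModel-class].
#' @param ... passed on to `predictActivityForest`.
#' @export
setMethod("predict", "ForestModel", function(object, ...) {
  predictActivityForest(object, ...)
})
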