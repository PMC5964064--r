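#' @import methods
NULL

#' Compound-by-assay activity matrix with an observed-cell mask
#'
#' The central container of the package: a dense numeric grid of activity
#' readouts (percent inhibition for regression tasks; 0/1 labels with
#' inactive = 0, active = 1 for classification tasks) together with a logical
#' mask marking which cells carry a measurement. Compound and assay
#' identifiers live in the dimnames of the value grid.
#'
#' @slot values numeric matrix, compounds in rows, assays in columns.
#'   Unobserved cells hold `NA`.
#' @slot observed logical matrix of the same dimension; `TRUE` where a
#'   measurement exists.
#' @slot taskType `"regression"` or `"classification"`.
#'
#' @seealso [ActivityMatrix()] for the constructor,
#'   [readActivityCsv()] / [writeActivityCsv()] for I/O.
#' @export
setClass("ActivityMatrix",
  representation(
    values   = "matrix",
    observed = "matrix",
    taskType = "character"
  )
)

setValidity("ActivityMatrix", function(object) {
  v <- object@values
  o <- object@observed
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
  if (!is.logical(o)) msgs <- c(msgs, "'observed' must be a logical matrix")
  if (!identical(dim(v), dim(o)))
    msgs <- c(msgs, "'values' and 'observed' must have identical dimensions")
  if (length(object@taskType) != 1L ||
      !object@taskType %in% c("regression", "classification"))
    msgs <- c(msgs, "taskType must be 'regression' or 'classification'")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry compound (row) and assay (column) names")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicate compound identifiers")
  if (anyDuplicated(colnames(v)))
    msgs <- c(msgs, "duplicate assay identifiers")
  if (identical(dim(v), dim(o)) && any(is.na(v[o])))
    msgs <- c(msgs, "observed cells must not be NA")
  if (length(msgs) == 0L && object@taskType == "classification") {
    obsv <- v[o]
    if (length(obsv) && !all(obsv %in% c(0, 1)))
      msgs <- c(msgs, "classification matrices may only contain 0/1 at observed cells")
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary substructure fingerprints paired with an activity matrix
#'
#' Hashed circular fingerprints (ECFP4-like, 1024 bits by default) stored as
#' a compounds-by-bits 0/1 integer matrix. Row names are compound
#' identifiers and must align with the rows of the paired
#' [ActivityMatrix-class].
#'
#' @slot bits integer matrix of 0/1 values; one row per compound.
#' @export
setClass("FingerprintSet", representation(bits = "matrix"))

setValidity("FingerprintSet", function(object) {
  b <- object@bits
  msgs <- character()
  if (!is.numeric(b)) msgs <- c(msgs, "'bits' must be a numeric 0/1 matrix")
  else if (!all(b %in% c(0, 1))) msgs <- c(msgs, "'bits' must contain only 0/1")
  if (is.null(rownames(b))) msgs <- c(msgs, "fingerprints must carry compound row names")
  if (anyDuplicated(rownames(b))) msgs <- c(msgs, "duplicate compound identifiers")
  if (is.numeric(b) && nrow(b) > 0 && any(rowSums(b) < 1))
    msgs <- c(msgs, "every fingerprint must have at least one bit set")
  if (length(msgs)) msgs else TRUE
})

#' Compound-level train/test partition of an activity matrix
#'
#' @slot train,test [ActivityMatrix-class] objects over disjoint compound
#'   sets whose union is the input compound set. Assays are untouched.
#' @slot splitSeed integer seed that produced the partition.
#' @export
setClass("SplitResult",
  representation(train = "ActivityMatrix", test = "ActivityMatrix",
                 splitSeed = "integer")
)

setValidity("SplitResult", function(object) {
  tr <- rownames(object@train@values)
  te <- rownames(object@test@values)
  if (length(intersect(tr, te)))
    return("train and test compound sets overlap")
  TRUE
})

#' Ground truth behind a synthetic dataset
#'
#' Kept alongside generated data so tests can score predictions against the
#' noiseless signal. `latentCompound %*% t(latentAssay)` is the rank-k signal
#' before noise and affine rescaling into response units.
#'
#' @slot latentCompound n x k numeric matrix of compound latent vectors.
#' @slot latentAssay m x k numeric matrix of assay latent vectors.
#' @slot link B x k numeric matrix mapping fingerprint bits to the
#'   fingerprint-driven part of the compound latents.
#' @slot thresholds per-assay activity thresholds (classification; empty for
#'   regression).
#' @slot offset,scale affine map applied to (signal + noise):
#'   `values = offset + scale * raw`.
#' @slot noiseSd additive noise standard deviation in latent (raw) units.
#' @slot noiseSdResponse the same noise after rescaling, i.e. in the units of
#'   the emitted activity values (`scale * noiseSd`).
#' @export
setClass("SyntheticTruth",
  representation(
    latentCompound = "matrix", latentAssay = "matrix", link = "matrix",
    thresholds = "numeric", offset = "numeric", scale = "numeric",
    noiseSd = "numeric", noiseSdResponse = "numeric"
  )
)

#' Posterior trace of the side-information matrix-factorization sampler
#'
#' Post burn-in Gibbs snapshots of the compound latents U, assay latents V,
#' the fingerprint link matrix beta and the compound prior mean. Predictions
#' average the reconstruction over the snapshots.
#'
#' @slot samples list of snapshots; each holds `U`, `V`, `beta`, `muU`.
#' @slot center,scaleFactor standardization of the observed training values
#'   undone at prediction time.
#' @slot assayIds assay identifiers defining prediction columns.
#' @slot taskType task type of the training matrix.
#' @slot config list echo of the fitting configuration.
#' @export
setClass("BPMFTrace",
  representation(samples = "list", center = "numeric", scaleFactor = "numeric",
                 assayIds = "character", taskType = "character",
                 config = "list")
)

setValidity("BPMFTrace", function(object) {
  if (length(object@samples) < 1L) return("trace must contain >= 1 sample")
  TRUE
})

#' Fully connected multitask network with a masked loss
#'
#' Weights of a fingerprint-in / activity-profile-out feed-forward network.
#' Unobserved cells contribute nothing to the training loss, so the model can
#' be fitted on matrices sparsified by label removal.
#'
#' @slot weights,biases per-layer parameter lists.
#' @slot activation `"relu"` or `"linear"` hidden activation.
#' @slot taskType `"regression"` (linear output) or `"classification"`
#'   (sigmoid output).
#' @slot assayIds output column identifiers.
#' @slot center,scaleFactor response standardization (regression only).
#' @slot finalLoss training loss at the last step.
#' @slot config list echo of the fitting configuration.
#' @export
setClass("MultitaskNet",
  representation(weights = "list", biases = "list", activation = "character",
                 taskType = "character", assayIds = "character",
                 center = "numeric", scaleFactor = "numeric",
                 finalLoss = "numeric", config = "list")
)

#' Per-assay tree-ensemble baseline
#'
#' One random-forest ensemble per assay over fingerprint bits. Requires a
#' complete training matrix (all cells observed), mirroring tree-ensemble
#' implementations that cannot accept missing outputs; it is therefore only
#' usable with the compound removal model (after assay-mean imputation of any
#' pre-existing missing cells).
#'
#' @slot forests list of per-assay fitted ensembles.
#' @slot taskType task type.
#' @slot assayIds output column identifiers.
#' @slot config list echo of the fitting configuration.
#' @export
setClass("ForestModel",
  representation(forests = "list", taskType = "character",
                 assayIds = "character", config = "list")
)
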