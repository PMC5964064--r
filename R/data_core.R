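#' @include utils.R
NULL

#' Construct an activity matrix
#'
#' @param values numeric matrix with compound row names and assay column
#'   names; `NA` marks unobserved cells when `observed` is not given.
#' @param observed optional logical mask; defaults to `!is.na(values)`.
#' @param taskType `"regression"` or `"classification"`.
#' @return an [ActivityMatrix-class].
#' @examples
#' v <- matrix(c(1, NA, 3, 4), 2, 2,
#'   dimnames = list(c("c1", "c2"), c("a1", "a2")))
#' ActivityMatrix(v)
#' @export
ActivityMatrix <- function(values, observed = NULL, taskType = "regression") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  values[!observed] <- NA_real_
  dimnames(observed) <- dimnames(values)
  new("ActivityMatrix", values = values, observed = observed,
      taskType = taskType)
}

#' Construct a fingerprint set
#'
#' @param bits 0/1 matrix, compounds in rows (row names required).
#' @return a [FingerprintSet-class].
#' @export
FingerprintSet <- function(bits) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  new("FingerprintSet", bits = bits)
}

#' @rdname activity-accessors
#' @export
setMethod("activityValues", "ActivityMatrix", function(x) x@values)

#' @rdname activity-accessors
#' @export
setMethod("observedMask", "ActivityMatrix", function(x) x@observed)

#' @rdname activity-accessors
#' @export
setMethod("taskType", "ActivityMatrix", function(x) x@taskType)

#' @rdname activity-accessors
#' @export
setMethod("compoundIds", "ActivityMatrix", function(x) rownames(x@values))

#' @rdname activity-accessors
#' @export
setMethod("assayIds", "ActivityMatrix", function(x) colnames(x@values))

#' @rdname activity-accessors
#' @export
setMethod("nObserved", "ActivityMatrix", function(x) sum(x@observed))

#' @rdname activity-accessors
#' @export
setMethod("compoundIds", "FingerprintSet", function(x) rownames(x@bits))

#' @export
#' @describeIn FingerprintSet bit matrix accessor
setMethod("fingerprintBits", "FingerprintSet", function(x) x@bits)

setMethod("dim", "ActivityMatrix", function(x) dim(x@values))

setMethod("show", "ActivityMatrix", function(object) {
  d <- dim(object@values)
  L <- sum(object@observed)
  cat(sprintf("ActivityMatrix (%s): %d compounds x %d assays, %d observed (%.2f%% filled)\n",
              object@taskType, d[1], d[2], L,
              if (prod(d) > 0) 100 * L / prod(d) else NA_real_))
})

setMethod("show", "FingerprintSet", function(object) {
  bs <- rowSums(object@bits)
  cat(sprintf("FingerprintSet: %d compounds x %d bits; bits set per compound: %d-%d (median %s)\n",
              nrow(object@bits), ncol(object@bits),
              if (length(bs)) min(bs) else NA, if (length(bs)) max(bs) else NA,
              if (length(bs)) format(stats::median(bs)) else NA))
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (seed %d): %d train / %d test compounds, %d assays\n",
              object@splitSeed, nrow(object@train@values),
              nrow(object@test@values), ncol(object@train@values)))
})

# Subset an activity matrix by row/column index, keeping mask and ids aligned.
subsetActivity <- function(x, i = NULL, j = NULL) {
  v <- x@values; o <- x@observed
  if (!is.null(i)) { v <- v[i, , drop = FALSE]; o <- o[i, , drop = FALSE] }
  if (!is.null(j)) { v <- v[, j, drop = FALSE]; o <- o[, j, drop = FALSE] }
  new("ActivityMatrix", values = v, observed = o, taskType = x@taskType)
}

#' Read a wide activity CSV
#'
#' Wide UTF-8 CSV: first column compound identifiers, header row assay
#' identifiers, one cell per compound-assay pair. The empty string is the
#' only missing-value token ("NA"/"NaN" are rejected). Classification cells
#' accept the tokens `active`/`inactive`/`1`/`0` and are stored as 1/0.
#'
#' @param path CSV file path.
#' @param taskType `"regression"` or `"classification"`.
#' @return an [ActivityMatrix-class].
#' @seealso [writeActivityCsv()]
#' @export
readActivityCsv <- function(path, taskType = c("regression", "classification")) {
  taskType <- match.arg(taskType)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  if (ncol(df) < 2L) stopfmt("activity CSV needs an id column plus >=1 assay column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopfmt("duplicate compound ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cells) <- ids
  observed <- cells != ""
  vals <- matrix(NA_real_, nrow(cells), ncol(cells), dimnames = dimnames(cells))
  if (taskType == "regression") {
    suppressWarnings(num <- as.numeric(cells[observed]))
    if (anyNA(num)) {
      bad <- which(observed, arr.ind = TRUE)[which(is.na(num))[1L], ]
      stopfmt("non-numeric regression value at compound '%s', assay '%s'",
              rownames(cells)[bad[1L]], colnames(cells)[bad[2L]])
    }
    vals[observed] <- num
  } else {
    tok <- tolower(trimws(cells[observed]))
    map <- c(active = 1, inactive = 0, "1" = 1, "0" = 0)
    if (!all(tok %in% names(map))) {
      badTok <- setdiff(unique(tok), names(map))[1L]
      stopfmt("unknown classification token '%s' (accepted: active, inactive, 1, 0)",
              badTok)
    }
    vals[observed] <- unname(map[tok])
  }
  new("ActivityMatrix", values = vals, observed = observed, taskType = taskType)
}

#' Write a wide activity CSV
#'
#' Inverse of [readActivityCsv()]: unobserved cells become empty strings;
#' classification values are written as 1/0.
#'
#' @param x an [ActivityMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeActivityCsv <- function(x, path) {
  v <- x@values
  cells <- matrix("", nrow(v), ncol(v), dimnames = dimnames(v))
  obs <- x@observed
  cells[obs] <- vapply(v[obs], function(z) format(z, digits = 15), character(1))
  df <- data.frame(compound_id = rownames(v), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a fingerprint CSV
#'
#' CSV with a compound id column followed by one 0/1 column per bit.
#'
#' @param path file path.
#' @return [FingerprintSet-class] (read) or `path` invisibly (write).
#' @export
readFingerprintCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  bits <- as.matrix(df[, -1L, drop = FALSE])
  rownames(bits) <- as.character(df[[1L]])
  FingerprintSet(bits)
}

#' @rdname readFingerprintCsv
#' @param x a [FingerprintSet-class].
#' @export
writeFingerprintCsv <- function(x, path) {
  df <- data.frame(compound_id = rownames(x@bits), x@bits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fillFraction
#' @export
setMethod("fillFraction", "ActivityMatrix", function(x, ...) {
  fillFraction(prod(dim(x@values)), nObservedCells = sum(x@observed))
})

#' @rdname fillFraction
#' @param nObservedCells observed-cell count L (count-based method).
#' @export
setMethod("fillFraction", "numeric", function(x, nObservedCells) {
  if (x <= 0) stopfmt("empty matrix: total cell count must be positive")
  if (nObservedCells < 0 || nObservedCells > x)
    stopfmt("observed count must lie in [0, total]")
  pm <- 100 * (x - nObservedCells) / x
  c(percentFilled = 100 - pm, percentMissing = pm)
})

#' Split compounds into train and test sets
#'
#' Random compound-level (row) partition; assays are never split. The study
#' design uses a 3:1 train:test ratio, holds the test rows out of all
#' downstream label removal, and evaluates per assay on the held-out
#' compounds.
#'
#' @param x an [ActivityMatrix-class] with >= 2 compounds.
#' @param testFraction fraction of compounds assigned to the test set
#'   (default 0.25); the test count is `round(testFraction * n)`, half away
#'   from zero.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return a [SplitResult-class].
#' @examples
#' am <- genRegressionMatrix(syntheticConfig(nCompounds = 40, nAssays = 6))$activity
#' sp <- trainTestSplit(am, seed = 1)
#' sp
#' @export
trainTestSplit <- function(x, testFraction = 0.25, seed) {
  stopifnot(is(x, "ActivityMatrix"))
  if (testFraction <= 0 || testFraction >= 1)
    stopfmt("testFraction must be in (0, 1)")
  n <- nrow(x@values)
  if (n < 2L) stopfmt("need at least 2 compounds to split")
  nTest <- roundHalfUp(testFraction * n)
  if (nTest < 1L || nTest >= n)
    stopfmt("split leaves a side with 0 compounds (n = %d, testFraction = %g)",
            n, testFraction)
  testIdx <- withSeed(seed, sort(sample.int(n, nTest)))
  new("SplitResult",
      train = subsetActivity(x, i = setdiff(seq_len(n), testIdx)),
      test  = subsetActivity(x, i = testIdx),
      splitSeed = as.integer(seed))
}

#' Pairwise Tanimoto similarity of binary fingerprints
#'
#' Tanimoto(a, b) = |a AND b| / |a OR b| over bit vectors. Pairs of all-zero
#' vectors are undefined and returned as `NA` (the package's fingerprint
#' containers forbid empty fingerprints, so this arises only on raw input).
#'
#' @param bits 0/1 matrix, one fingerprint per row, or a
#'   [FingerprintSet-class].
#' @return symmetric n x n similarity matrix.
#' @export
tanimotoSimilarity <- function(bits) {
  if (is(bits, "FingerprintSet")) bits <- bits@bits
  b <- bits
  storage.mode(b) <- "double"
  inter <- tcrossprod(b)
  cnt <- rowSums(b)
  uni <- outer(cnt, cnt, "+") - inter
  out <- inter / uni
  out[uni == 0] <- NA_real_
  out
}

#' Descriptive statistics of a dataset
#'
#' Summarizes an activity matrix and its paired fingerprints the way
#' profiling datasets are usually characterized: value range and the fraction
#' of values inside \[0, 100] (regression), per-assay active:inactive ratios
#' (classification), bits-set distribution, and the pairwise Tanimoto
#' similarity distribution.
#'
#' @param x an [ActivityMatrix-class].
#' @param fps the paired [FingerprintSet-class].
#' @return a list with components `valueRange`, `fractionIn0to100`,
#'   `activeRatios`, `bitsSet` (min/mean/median/max) and `tanimoto`
#'   (min/mean/median/max over distinct pairs).
#' @export
describeDataset <- function(x, fps) {
  stopifnot(is(x, "ActivityMatrix"), is(fps, "FingerprintSet"))
  if (!identical(rownames(x@values), rownames(fps@bits)))
    stopfmt("activity matrix and fingerprints are not aligned")
  obsVals <- x@values[x@observed]
  res <- list()
  if (x@taskType == "regression") {
    res$valueRange <- range(obsVals)
    res$fractionIn0to100 <- mean(obsVals >= 0 & obsVals <= 100)
    res$activeRatios <- NULL
  } else {
    res$valueRange <- range(obsVals)
    res$fractionIn0to100 <- NA_real_
    nAct <- colSums(x@values == 1 & x@observed)
    nInact <- colSums(x@values == 0 & x@observed)
    res$activeRatios <- nAct / nInact
  }
  bs <- rowSums(fps@bits)
  res$bitsSet <- c(min = min(bs), mean = mean(bs),
                   median = stats::median(bs), max = max(bs))
  tm <- tanimotoSimilarity(fps)
  pairVals <- tm[upper.tri(tm)]
  res$tanimoto <- c(min = min(pairVals), mean = mean(pairVals),
                    median = stats::median(pairVals), max = max(pairVals))
  res
}
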