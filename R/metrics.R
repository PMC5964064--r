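#' @include data_core.R
NULL

# Direction of "worse" per metric: +1 means larger is worse (errors), -1
# means smaller is worse (quality scores). One crossing rule serves every
# progression figure.
metricDirection <- function(metric) {
  dirs <- c(rmsd = 1, mae = 1, r2 = -1, rho2 = -1,
            precision = -1, recall = -1, f1 = -1, mcc = -1)
  if (!metric %in% names(dirs)) stopfmt("unknown metric '%s'", metric)
  unname(dirs[metric])
}

#' Per-assay regression scores
#'
#' RMSD = sqrt(mean((y - yhat)^2)), MAE = mean(|y - yhat|), R2 = 1 -
#' SS_res/SS_tot, rho2 = squared Pearson correlation. Assays whose observed
#' values have zero variance get `NA` for R2 and rho2 (undefined; excluded
#' from medians downstream).
#'
#' @param yTrue,yPred numeric matrices (compounds x assays) or vectors; `NA`
#'   in `yTrue` marks cells excluded from scoring.
#' @return data.frame with one row per assay: `assay_id`, `n`, `rmsd`, `mae`,
#'   `r2`, `rho2`.
#' @export
regressionScores <- function(yTrue, yPred) {
  yTrue <- as.matrix(yTrue); yPred <- as.matrix(yPred)
  if (!identical(dim(yTrue), dim(yPred)))
    stopfmt("yTrue and yPred must have identical dimensions")
  ids <- colnames(yTrue)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(yTrue)))
  out <- lapply(seq_len(ncol(yTrue)), function(j) {
    ok <- !is.na(yTrue[, j]) & !is.na(yPred[, j])
    y <- yTrue[ok, j]; p <- yPred[ok, j]
    n <- length(y)
    if (n == 0L)
      return(data.frame(assay_id = ids[j], n = 0L, rmsd = NA_real_,
                        mae = NA_real_, r2 = NA_real_, rho2 = NA_real_))
    res <- y - p
    rmsd <- sqrt(mean(res^2)); mae <- mean(abs(res))
    sst <- sum((y - mean(y))^2)
    if (n >= 2L && sst > 0) {
      r2 <- 1 - sum(res^2) / sst
      rho2 <- if (stats::sd(p) > 0) stats::cor(y, p)^2 else NA_real_
    } else {
      r2 <- NA_real_; rho2 <- NA_real_
    }
    data.frame(assay_id = ids[j], n = n, rmsd = rmsd, mae = mae,
               r2 = r2, rho2 = rho2)
  })
  do.call(rbind, out)
}

#' Per-assay binary classification scores
#'
#' From confusion counts (active = 1 is the positive class): precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R), MCC =
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any zero
#' denominator yields a score of 0 (the conventional bounded-metric rule).
#'
#' @param yTrue,yPred 0/1 matrices (compounds x assays) or vectors; `NA` in
#'   `yTrue` marks excluded cells.
#' @return data.frame with one row per assay: `assay_id`, `n`, `tp`, `tn`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`, `mcc`.
#' @export
classificationScores <- function(yTrue, yPred) {
  yTrue <- as.matrix(yTrue); yPred <- as.matrix(yPred)
  if (!identical(dim(yTrue), dim(yPred)))
    stopfmt("yTrue and yPred must have identical dimensions")
  ids <- colnames(yTrue)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(yTrue)))
  out <- lapply(seq_len(ncol(yTrue)), function(j) {
    ok <- !is.na(yTrue[, j]) & !is.na(yPred[, j])
    y <- yTrue[ok, j]; p <- yPred[ok, j]
    if (!all(y %in% c(0, 1)) || !all(p %in% c(0, 1)))
      stopfmt("labels must be 0/1 (assay '%s')", ids[j])
    tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
    fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
    safeDiv <- function(num, den) if (den == 0) 0 else num / den
    prec <- safeDiv(tp, tp + fp)
    rec <- safeDiv(tp, tp + fn)
    f1 <- safeDiv(2 * prec * rec, prec + rec)
    mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
    data.frame(assay_id = ids[j], n = length(y), tp = tp, tn = tn, fp = fp,
               fn = fn, precision = prec, recall = rec, f1 = f1, mcc = mcc)
  })
  do.call(rbind, out)
}

#' Score predictions against a test activity matrix
#'
#' Convenience wrapper dispatching on the task type; only observed test cells
#' are scored.
#'
#' @param test an [ActivityMatrix-class] (typically the held-out split).
#' @param predictions numeric matrix aligned with `test` (classification
#'   predictions already thresholded to 0/1).
#' @return per-assay score data.frame (see [regressionScores()] /
#'   [classificationScores()]).
#' @export
scorePredictions <- function(test, predictions) {
  stopifnot(is(test, "ActivityMatrix"))
  truth <- test@values
  truth[!test@observed] <- NA_real_
  predictions <- as.matrix(predictions)
  if (!identical(dim(truth), dim(predictions)))
    stopfmt("predictions are not aligned with the test matrix")
  if (test@taskType == "regression") regressionScores(truth, predictions)
  else classificationScores(truth, predictions)
}

#' Median-across-assays progression curve, absolute and relative
#'
#' Collapses per-assay scores to the median per removal fraction and divides
#' by the complete-data (fraction 0) median, so a relative value of 1.10 on
#' an error metric reads "10 percent worse than the model trained on all data".
#' Assays with undefined (`NA`) scores are excluded from the medians.
#'
#' @param scores data.frame with at least columns `fraction`, `assay_id` and
#'   the metric column.
#' @param metric metric column name (e.g. `"rmsd"`, `"mcc"`).
#' @param method,removalModel optional labels carried into the curve.
#' @return data.frame of class `ProgressionCurve` with columns `fraction`,
#'   `median`, `relative`, plus `metric`, `method`, `removal_model`
#'   attributes as columns.
#' @export
aggregateScores <- function(scores, metric, method = NA_character_,
                            removalModel = NA_character_) {
  if (!metric %in% names(scores)) stopfmt("no column '%s' in scores", metric)
  if (!"fraction" %in% names(scores)) stopfmt("scores need a 'fraction' column")
  fr <- sort(unique(scores$fraction))
  if (!0 %in% fr) stopfmt("complete-data run (fraction 0) missing")
  med <- vapply(fr, function(f) {
    stats::median(scores[[metric]][scores$fraction == f], na.rm = TRUE)
  }, numeric(1))
  base <- med[fr == 0]
  if (is.na(base)) stopfmt("complete-data median is undefined")
  curve <- data.frame(fraction = fr, median = med, relative = med / base,
                      metric = metric, method = method,
                      removal_model = removalModel,
                      stringsAsFactors = FALSE)
  class(curve) <- c("ProgressionCurve", "data.frame")
  curve
}

#' First removal fraction at which performance degrades by a given amount
#'
#' Returns the smallest grid fraction whose relative metric is worse than
#' `1 + relChange` (error metrics, where larger is worse) or `1 - relChange`
#' (quality metrics). No interpolation between grid points; `NA` if the
#' curve never crosses.
#'
#' @param curve a curve from [aggregateScores()] (columns `fraction`,
#'   `relative`, `metric`).
#' @param relChange relative degradation, e.g. 0.10 for "10 percent worse".
#' @return the crossing fraction, or `NA` if never crossed.
#' @export
thresholdCrossing <- function(curve, relChange = 0.10) {
  stopifnot(all(c("fraction", "relative") %in% names(curve)))
  if (is.unsorted(curve$fraction)) curve <- curve[order(curve$fraction), ]
  dir <- metricDirection(curve$metric[1L])
  worse <- if (dir > 0) curve$relative > 1 + relChange
           else curve$relative < 1 - relChange
  worse[is.na(worse)] <- FALSE
  idx <- which(worse)
  if (length(idx) == 0L) NA_real_ else curve$fraction[idx[1L]]
}
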