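#' @include AllClasses.R
NULL

#' Accessors for activity matrices and fingerprints
#'
#' `activityValues()` returns the numeric value grid (with `NA` at unobserved
#' cells), `observedMask()` the logical mask, `taskType()` the task kind,
#' `compoundIds()` / `assayIds()` the identifiers, and `nObserved()` the number
#' of observed cells L.
#'
#' @param x an [ActivityMatrix-class] or [FingerprintSet-class] object.
#' @return see individual descriptions.
#' @name activity-accessors
#' @aliases activityValues observedMask taskType compoundIds assayIds nObserved
#' @examples
#' am <- ActivityMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("c1", "c2"), c("a1", "a2", "a3"))))
#' nObserved(am)
#' compoundIds(am)
NULL

#' @rdname activity-accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname activity-accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname activity-accessors
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' @rdname activity-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname activity-accessors
#' @export
setGeneric("assayIds", function(x) standardGeneric("assayIds"))

#' @rdname activity-accessors
#' @export
setGeneric("nObserved", function(x) standardGeneric("nObserved"))

#' Fingerprint bit matrix accessor
#'
#' @param x a [FingerprintSet-class].
#' @return the compounds-by-bits 0/1 matrix.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' Fraction of the activity grid that is observed / missing
#'
#' Reports what percentage of the n x m grid carries a measurement. A kinase
#' panel missing 87 of 367 x 454 cells is 0.05% missing; the Netflix-prize
#' rating matrix (~1e8 ratings of 480,000 x 17,000 user-movie pairs) is 1.2%
#' filled.
#'
#' @param x an [ActivityMatrix-class], or the total number of cells
#'   (`numeric`) when calling the count-based method.
#' @param ... for the count-based method: `nObservedCells`, the number of
#'   observed cells.
#' @return named numeric vector `c(percentFilled=, percentMissing=)`, on the
#'   0-100 scale; the two entries sum to 100 exactly.
#' @examples
#' fillFraction(367 * 454, nObservedCells = 367 * 454 - 87)
#' @export
setGeneric("fillFraction", function(x, ...) standardGeneric("fillFraction"))
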