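#' @include data_core.R
NULL

#' Removal-fraction grids and the seed-control design
#'
#' A sparsification plan names one of the three removal models, an increasing
#' fraction grid starting at 0 (the complete-data reference), and a removal
#' seed. `sparsifyPlan()` validates and returns it as a plain list. The
#' default grids match the study design: 101 levels (0.00-1.00, step 0.01)
#' for the regression panel, 40 levels (0.000-0.975, step 0.025) for the
#' screening-profile subsets. Each fraction is sampled independently (grids
#' are not nested deletions of one permutation).
#'
#' @param removalModel `"label"`, `"compound"` or `"assay"`.
#' @param fractions strictly increasing removal fractions in \[0, 1], first
#'   element 0.
#' @param removalSeed integer seed for the removal draws.
#' @return list of class `SparsifyPlan`.
#' @export
sparsifyPlan <- function(removalModel = c("label", "compound", "assay"),
                         fractions = seq(0, 1, by = 0.01),
                         removalSeed = 1L) {
  removalModel <- match.arg(removalModel)
  if (length(fractions) < 1L || fractions[1L] != 0)
    stopfmt("fraction grid must start at 0 (complete-data reference)")
  if (is.unsorted(fractions, strictly = TRUE))
    stopfmt("fractions must be strictly increasing")
  if (any(fractions < 0 | fractions > 1))
    stopfmt("fractions must lie in [0, 1]")
  structure(list(removalModel = removalModel, fractions = fractions,
                 removalSeed = as.integer(removalSeed)),
            class = "SparsifyPlan")
}

#' Default fraction grids of the study design
#'
#' @param dataset `"pkis"` (101 levels, step 0.01) or `"htsfp"` (40 levels,
#'   step 0.025).
#' @return numeric fraction grid starting at 0.
#' @export
defaultFractionGrid <- function(dataset = c("pkis", "htsfp")) {
  switch(match.arg(dataset),
         pkis = seq(0, 1, by = 0.01),
         htsfp = seq(0, 0.975, by = 0.025))
}

#' Remove individual activity labels at random
#'
#' Clears `round(fraction * L)` observed cells chosen uniformly without
#' replacement. The matrix keeps its size but becomes sparse; retained
#' values are untouched.
#'
#' @param x training [ActivityMatrix-class].
#' @param fraction removal fraction in \[0, 1].
#' @param seed integer seed; deterministic given the seed.
#' @return a sparser [ActivityMatrix-class] of identical dimensions.
#' @seealso [removeCompounds()], [removeAssays()], [auditEmpty()]
#' @export
removeLabels <- function(x, fraction, seed) {
  stopifnot(is(x, "ActivityMatrix"))
  if (fraction < 0 || fraction > 1) stopfmt("fraction must be in [0, 1]")
  obsIdx <- which(x@observed)
  nRemove <- roundHalfUp(fraction * length(obsIdx))
  if (nRemove == 0L) return(x)
  drop <- withSeed(seed, sample(obsIdx, nRemove))
  observed <- x@observed
  observed[drop] <- FALSE
  vals <- x@values
  vals[!observed] <- NA_real_
  new("ActivityMatrix", values = vals, observed = observed,
      taskType = x@taskType)
}

#' Remove whole compounds (rows) at random
#'
#' Drops `round(fraction * n)` rows; the remaining matrix is smaller but its
#' observed pattern is untouched (a complete matrix stays complete).
#'
#' @inheritParams removeLabels
#' @return an [ActivityMatrix-class] with fewer rows.
#' @export
removeCompounds <- function(x, fraction, seed) {
  stopifnot(is(x, "ActivityMatrix"))
  if (fraction < 0 || fraction >= 1) stopfmt("fraction must be in [0, 1)")
  n <- nrow(x@values)
  nRemove <- roundHalfUp(fraction * n)
  if (nRemove == 0L) return(x)
  if (nRemove >= n) stopfmt("compound removal would drop every compound")
  drop <- withSeed(seed, sample.int(n, nRemove))
  subsetActivity(x, i = setdiff(seq_len(n), drop))
}

#' Remove whole assays (columns) at random
#'
#' Drops `round(fraction * m)` columns; evaluation downstream is restricted
#' to the surviving assays. Intended for many-assay regression panels; with
#' very few assays the grid collapses.
#'
#' @inheritParams removeLabels
#' @return an [ActivityMatrix-class] with fewer columns.
#' @export
removeAssays <- function(x, fraction, seed) {
  stopifnot(is(x, "ActivityMatrix"))
  if (fraction < 0 || fraction >= 1) stopfmt("fraction must be in [0, 1)")
  m <- ncol(x@values)
  if (m < 2L) stopfmt("need >= 2 assays for assay removal")
  nRemove <- roundHalfUp(fraction * m)
  if (nRemove == 0L) return(x)
  if (nRemove >= m) stopfmt("assay removal would drop every assay")
  drop <- withSeed(seed, sample.int(m, nRemove))
  subsetActivity(x, j = setdiff(seq_len(m), drop))
}

# Dispatch helper used by the orchestrator.
applyRemoval <- function(x, model, fraction, seed) {
  switch(model,
         label = removeLabels(x, fraction, seed),
         compound = removeCompounds(x, fraction, seed),
         assay = removeAssays(x, fraction, seed),
         stopfmt("unknown removal model '%s'", model))
}

#' List assays and compounds left without any observed label
#'
#' After heavy label removal some assays (or compounds) can end up with no
#' activity annotation at all, at which point the predictors cannot be
#' trained for them; fitting consults this report and fails (or prunes)
#' accordingly.
#'
#' @param x an [ActivityMatrix-class].
#' @return list with character vectors `emptyAssays` and `emptyCompounds`.
#' @export
auditEmpty <- function(x) {
  stopifnot(is(x, "ActivityMatrix"))
  list(emptyAssays = colnames(x@values)[colSums(x@observed) == 0L],
       emptyCompounds = rownames(x@values)[rowSums(x@observed) == 0L])
}

#' Expected number of empty assays after label removal
#'
#' For a fully observed n x m matrix with r = round(f * n * m) labels removed
#' uniformly at random, the probability that a given assay loses all n of its
#' labels is `choose(nm - n, r - n) / choose(nm, r)`, so the expected number
#' of empty assays is m times that. Computed in log space.
#'
#' @param n,m matrix dimensions.
#' @param fraction removal fraction f.
#' @return expected count of empty assays.
#' @export
expectedEmptyAssays <- function(n, m, fraction) {
  total <- as.numeric(n) * m
  r <- roundHalfUp(fraction * total)
  if (r < n) return(0)
  m * exp(lchoose(total - n, r - n) - lchoose(total, r))
}
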