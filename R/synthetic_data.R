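#' @include data_core.R
NULL

#' Configuration for the synthetic dataset generator
#'
#' Describes a complete multitask activity dataset with low-rank inter-assay
#' structure and a fingerprint-linked compound signal. The generator's role
#' is to emulate the printed statistical descriptors of the study datasets
#' (value ranges, class ratios, bits-set distribution, pairwise Tanimoto
#' similarity), not real pharmacology; see the methods vignette.
#'
#' @param nCompounds,nAssays matrix dimensions before any exclusion.
#' @param latentRank true rank k of the signal matrix.
#' @param assayClusters number of groups of correlated assays
#'   (`latentRank >= assayClusters >= 1`).
#' @param clusterStrength in \[0, 1): share of each assay latent vector's
#'   variance contributed by its cluster mean; the within-cluster correlation
#'   knob.
#' @param noiseSd additive Gaussian noise sd, in latent (raw) units where the
#'   signal element sd is about `sqrt(latentRank)`.
#' @param signalFromFingerprint s in \[0, 1]: compound latents are
#'   `s * (bits %*% link) + (1 - s) * independent`, both parts standardized,
#'   so s = 1 makes activity an exact function of the fingerprints.
#' @param valueRange `(low, high)` response bounds for regression output;
#'   values are affinely rescaled and clipped into this range (clipping
#'   emulates assay saturation).
#' @param fractionIn0to100 regression only: target fraction of emitted values
#'   inside \[0, 100]; the affine map sends the matching central quantiles of
#'   the raw values to 0 and 100.
#' @param targetActiveRatios classification only: per-assay active:inactive
#'   target ratios (length `nAssays`).
#' @param bitsSetRange integer `(min, median, max)` bits set per fingerprint.
#' @param nBits fingerprint length B (default 1024).
#' @param tanimotoTarget desired mean pairwise Tanimoto similarity.
#' @param missingFraction regression only: fraction of cells left unobserved
#'   (default 5e-4, the order seen in curated kinase panels).
#' @param compoundClusterSize approximate number of compounds sharing a
#'   scaffold bit pool.
#' @param seed integer seed; all generator output is reproducible given
#'   (config, seed).
#' @return a validated list of class `SyntheticConfig`.
#' @seealso [syntheticPreset()] for ready-made configurations.
#' @export
syntheticConfig <- function(nCompounds, nAssays, latentRank = 3L,
                            assayClusters = 2L, clusterStrength = 0.5,
                            noiseSd = 0.45, signalFromFingerprint = 0.7,
                            valueRange = c(-77, 130), fractionIn0to100 = 0.8,
                            targetActiveRatios = NULL,
                            bitsSetRange = c(26L, 52L, 88L), nBits = 1024L,
                            tanimotoTarget = 0.15, missingFraction = 5e-4,
                            compoundClusterSize = 15L, seed = 1L) {
  cfg <- list(nCompounds = as.integer(nCompounds), nAssays = as.integer(nAssays),
              latentRank = as.integer(latentRank),
              assayClusters = as.integer(assayClusters),
              clusterStrength = clusterStrength, noiseSd = noiseSd,
              signalFromFingerprint = signalFromFingerprint,
              valueRange = valueRange, fractionIn0to100 = fractionIn0to100,
              targetActiveRatios = targetActiveRatios,
              bitsSetRange = as.integer(bitsSetRange), nBits = as.integer(nBits),
              tanimotoTarget = tanimotoTarget,
              missingFraction = missingFraction,
              compoundClusterSize = as.integer(compoundClusterSize),
              seed = as.integer(seed))
  if (cfg$nCompounds < 2L || cfg$nAssays < 1L)
    stopfmt("need >= 2 compounds and >= 1 assay")
  if (cfg$latentRank < cfg$assayClusters || cfg$assayClusters < 1L)
    stopfmt("latentRank >= assayClusters >= 1 required")
  if (cfg$noiseSd < 0) stopfmt("noiseSd must be >= 0")
  if (cfg$signalFromFingerprint < 0 || cfg$signalFromFingerprint > 1)
    stopfmt("signalFromFingerprint must be in [0, 1]")
  if (length(cfg$bitsSetRange) != 3L || is.unsorted(cfg$bitsSetRange))
    stopfmt("bitsSetRange must be (min, median, max), non-decreasing")
  if (cfg$bitsSetRange[3L] > cfg$nBits)
    stopfmt("bitsSetRange exceeds fingerprint length")
  if (!is.null(cfg$targetActiveRatios)) {
    if (length(cfg$targetActiveRatios) != cfg$nAssays)
      stopfmt("targetActiveRatios must have one entry per assay")
    if (any(cfg$targetActiveRatios <= 0)) stopfmt("active ratios must be > 0")
  }
  if (cfg$clusterStrength < 0 || cfg$clusterStrength >= 1)
    stopfmt("clusterStrength must be in [0, 1)")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Ready-made generator configurations
#'
#' `"pkis_like"`: a 367 x 454 kinase percent-inhibition panel; values span
#' \[-77, 130] with ~80 percent inside \[0, 100], ~0.05 percent pre-existing missing cells,
#' fingerprints with 26-88 bits set (median 52) and mean pairwise Tanimoto
#' ~0.15. `"htsfp5_like"` / `"htsfp10_like"`: binary screening profiles over
#' 5 or 10 assays with active:inactive ratios spanning \[0.25, 2.9] and
#' \[0.14, 1.9], every compound active in at least one assay, fingerprints
#' with 12-102 bits set (median 43) and mean Tanimoto ~0.14.
#'
#' @param name one of `"pkis_like"`, `"htsfp5_like"`, `"htsfp10_like"`.
#' @param ... overrides passed to [syntheticConfig()] (commonly `nCompounds`
#'   and `seed`, to work at reduced scale).
#' @return a `SyntheticConfig`.
#' @export
syntheticPreset <- function(name = c("pkis_like", "htsfp5_like", "htsfp10_like"),
                            ...) {
  name <- match.arg(name)
  base <- switch(name,
    pkis_like = list(nCompounds = 367L, nAssays = 454L, latentRank = 3L,
                     assayClusters = 3L, clusterStrength = 0.5,
                     noiseSd = 0.45, signalFromFingerprint = 0.7,
                     valueRange = c(-77, 130), fractionIn0to100 = 0.8,
                     bitsSetRange = c(26L, 52L, 88L), tanimotoTarget = 0.15,
                     missingFraction = 5e-4),
    htsfp5_like = list(nCompounds = 49713L, nAssays = 5L, latentRank = 3L,
                       assayClusters = 2L, clusterStrength = 0.5,
                       noiseSd = 0.45, signalFromFingerprint = 0.7,
                       targetActiveRatios = c(2.9, 1.5, 0.8, 0.4, 0.25),
                       bitsSetRange = c(12L, 43L, 102L),
                       tanimotoTarget = 0.14),
    htsfp10_like = list(nCompounds = 56892L, nAssays = 10L, latentRank = 4L,
                        assayClusters = 3L, clusterStrength = 0.5,
                        noiseSd = 0.45, signalFromFingerprint = 0.7,
                        targetActiveRatios = c(1.9, 1.4, 1.0, 0.7, 0.5,
                                               0.35, 0.25, 0.2, 0.16, 0.14),
                        bitsSetRange = c(12L, 43L, 102L),
                        tanimotoTarget = 0.14))
  args <- utils::modifyList(base, list(...))
  do.call(syntheticConfig, args)
}

# Number of bits shared by every compound so that the mean pairwise Tanimoto
# lands near the target: solve T = (g + r) / (2c - g - r) with r the expected
# random-bit overlap (c - g)^2 / B, two fixed-point passes.
globalBitBudget <- function(medianBits, nBits, target) {
  if (target <= 0) return(0L)
  tot <- target * 2 * medianBits / (1 + target) # shared bits needed in total
  g <- tot
  for (i in 1:3) g <- tot - (medianBits - g)^2 / nBits
  max(0L, min(as.integer(round(g)), medianBits - 2L))
}

#' Generate binary fingerprints
#'
#' Per-compound bits-set counts are drawn to match the configured
#' (min, median, max); a shared global bit pool plus per-cluster "scaffold"
#' bits push the mean pairwise Tanimoto similarity toward the configured
#' target, with the remaining bits placed at random.
#'
#' @param config a [syntheticConfig()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return a [FingerprintSet-class].
#' @export
genFingerprints <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(seed, genFingerprintsImpl(config))
}

genFingerprintsImpl <- function(config, ids = NULL) {
  n <- config$nCompounds; B <- config$nBits
  rng <- config$bitsSetRange
  g <- globalBitBudget(rng[2L], B, config$tanimotoTarget)
  if (g >= rng[1L]) g <- max(0L, rng[1L] - 2L)
  scafPool <- 20L
  nClust <- max(1L, round(n / config$compoundClusterSize))
  if (rng[3L] > B) stopfmt("infeasible bit budget: max bits set exceeds B")
  # disjoint pools: global bits first, then cluster scaffolds, rest random
  perm <- sample.int(B)
  globalBits <- if (g > 0L) perm[seq_len(g)] else integer(0)
  scafAvail <- perm[(g + 1L):B]
  scafBits <- vector("list", nClust)
  pos <- 1L
  for (cl in seq_len(nClust)) {
    take <- min(scafPool, length(scafAvail) - pos + 1L)
    scafBits[[cl]] <- scafAvail[pos:(pos + take - 1L)]
    pos <- pos + take
    if (pos > length(scafAvail)) pos <- 1L  # wrap for very many clusters
  }
  clusterOf <- sample(rep_len(seq_len(nClust), n))
  # counts: half uniform on [min, median], half on [median, max]
  # (sample() from the candidate vector, guarding the length-1 case)
  drawCounts <- function(lo, hi, howMany) {
    cand <- seq.int(lo, hi)
    if (length(cand) == 1L) rep.int(cand, howMany)
    else sample(cand, howMany, replace = TRUE)
  }
  lowHalf <- stats::runif(n) < 0.5
  counts <- integer(n)
  counts[lowHalf] <- drawCounts(rng[1L], rng[2L], sum(lowHalf))
  counts[!lowHalf] <- drawCounts(rng[2L], rng[3L], sum(!lowHalf))
  bits <- matrix(0L, n, B)
  for (i in seq_len(n)) {
    ci <- counts[i]
    chosen <- globalBits[seq_len(min(g, ci))]
    rem <- ci - length(chosen)
    sc <- scafBits[[clusterOf[i]]]
    nSc <- min(length(sc), roundHalfUp(0.25 * rem))
    if (nSc > 0L) chosen <- c(chosen, sample(sc, nSc))
    rem <- ci - length(chosen)
    if (rem > 0L) {
      free <- setdiff(seq_len(B), chosen)
      chosen <- c(chosen, sample(free, rem))
    }
    bits[i, chosen] <- 1L
  }
  if (is.null(ids)) ids <- sprintf("cpd_%04d", seq_len(n))
  rownames(bits) <- ids
  colnames(bits) <- sprintf("bit_%04d", seq_len(B))
  FingerprintSet(bits)
}

# Latent compound/assay factors shared by both generators. Compound latents
# mix a fingerprint-driven linear part with an independent part; assay
# latents share cluster means so within-cluster assays correlate.
genLatents <- function(config, fps) {
  n <- config$nCompounds; m <- config$nAssays; k <- config$latentRank
  B <- config$nBits; s <- config$signalFromFingerprint
  link <- matrix(stats::rnorm(B * k), B, k)
  drive <- fingerprintBits(fps) %*% link
  driveSd <- apply(drive, 2L, stats::sd)
  driveSd[driveSd == 0] <- 1
  drive <- sweep(sweep(drive, 2L, colMeans(drive)), 2L, driveSd, "/")
  indep <- matrix(stats::rnorm(n * k), n, k)
  Zu <- s * drive + (1 - s) * indep
  w <- config$clusterStrength
  clusterOf <- rep_len(seq_len(config$assayClusters), m)
  mu <- matrix(stats::rnorm(config$assayClusters * k), config$assayClusters, k)
  Zv <- sqrt(w) * mu[clusterOf, , drop = FALSE] +
        sqrt(1 - w) * matrix(stats::rnorm(m * k), m, k)
  list(Zu = Zu, Zv = Zv, link = link)
}

#' Generate a complete regression activity matrix
#'
#' Builds a rank-`latentRank` signal `Zu %*% t(Zv)` from fingerprint-linked
#' compound latents and cluster-correlated assay latents, adds Gaussian
#' noise, and affinely rescales into `valueRange` with the map calibrated so
#' that `fractionIn0to100` of the values fall inside \[0, 100] (values beyond
#' the range are clipped, emulating assay saturation). A small fraction of
#' cells is left unobserved per `missingFraction`.
#'
#' @param config a [syntheticConfig()].
#' @param seed optional seed override.
#' @return list with `activity` ([ActivityMatrix-class]), `fingerprints`
#'   ([FingerprintSet-class]) and `truth` ([SyntheticTruth-class]).
#' @examples
#' out <- genRegressionMatrix(syntheticConfig(nCompounds = 50, nAssays = 8,
#'                                            seed = 7))
#' out$activity
#' @export
genRegressionMatrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(seed, {
    fps <- genFingerprintsImpl(config)
    lat <- genLatents(config, fps)
    n <- config$nCompounds; m <- config$nAssays
    raw <- lat$Zu %*% t(lat$Zv)
    if (config$noiseSd > 0)
      raw <- raw + matrix(stats::rnorm(n * m, sd = config$noiseSd), n, m)
    fIn <- config$fractionIn0to100
    qs <- stats::quantile(raw, c((1 - fIn) / 2, 1 - (1 - fIn) / 2), names = FALSE)
    if (qs[2L] <= qs[1L]) stopfmt("degenerate raw values; increase size or noise")
    scale <- 100 / (qs[2L] - qs[1L])
    offset <- -scale * qs[1L]
    vals <- offset + scale * raw
    vals <- pmin(pmax(vals, config$valueRange[1L]), config$valueRange[2L])
    dimnames(vals) <- list(compoundIds(fps), sprintf("assay_%04d", seq_len(m)))
    observed <- matrix(TRUE, n, m, dimnames = dimnames(vals))
    nMiss <- roundHalfUp(config$missingFraction * n * m)
    if (nMiss > 0L) observed[sample.int(n * m, nMiss)] <- FALSE
    truth <- new("SyntheticTruth", latentCompound = lat$Zu,
                 latentAssay = lat$Zv, link = lat$link,
                 thresholds = numeric(0), offset = offset, scale = scale,
                 noiseSd = config$noiseSd,
                 noiseSdResponse = scale * config$noiseSd)
    list(activity = ActivityMatrix(vals, observed, "regression"),
         fingerprints = fps, truth = truth)
  })
}

#' Generate a complete classification activity matrix
#'
#' Latent scores are thresholded per assay so empirical active:inactive
#' ratios match `targetActiveRatios`; compounds active in no assay are
#' excluded (with their fingerprints) and the thresholds re-estimated on the
#' retained compounds until the retained set stabilizes, so the emitted
#' ratios refer to the emitted matrix.
#'
#' @inheritParams genRegressionMatrix
#' @return list with `activity`, `fingerprints`, `truth`; the activity matrix
#'   may have fewer rows than `config$nCompounds` because of the exclusion
#'   rule, and every remaining compound is active in at least one assay.
#' @export
genClassificationMatrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(config$targetActiveRatios))
    stopfmt("classification generation needs targetActiveRatios")
  withSeed(seed, {
    fps <- genFingerprintsImpl(config)
    lat <- genLatents(config, fps)
    n <- config$nCompounds; m <- config$nAssays
    score <- lat$Zu %*% t(lat$Zv)
    if (config$noiseSd > 0)
      score <- score + matrix(stats::rnorm(n * m, sd = config$noiseSd), n, m)
    pActive <- config$targetActiveRatios / (1 + config$targetActiveRatios)
    kept <- rep(TRUE, n)
    thresholds <- numeric(m)
    for (iter in 1:25) {
      for (j in seq_len(m)) {
        sj <- score[kept, j]
        if (max(sj) - min(sj) < 1e-12)
          stopfmt("assay %d has degenerate scores; target ratio unreachable", j)
        thresholds[j] <- stats::quantile(sj, 1 - pActive[j], names = FALSE)
      }
      labels <- sweep(score, 2L, thresholds, ">")
      newKept <- kept & rowSums(labels) > 0
      if (identical(newKept, kept)) break
      kept <- newKept
      if (sum(kept) < 2L) stopfmt("exclusion rule removed nearly all compounds")
    }
    labels <- labels[kept, , drop = FALSE]
    vals <- matrix(as.numeric(labels), nrow(labels), m)
    dimnames(vals) <- list(compoundIds(fps)[kept],
                           sprintf("assay_%04d", seq_len(m)))
    fpsKept <- FingerprintSet(fingerprintBits(fps)[kept, , drop = FALSE])
    truth <- new("SyntheticTruth",
                 latentCompound = lat$Zu[kept, , drop = FALSE],
                 latentAssay = lat$Zv, link = lat$link,
                 thresholds = thresholds, offset = 0, scale = 1,
                 noiseSd = config$noiseSd, noiseSdResponse = config$noiseSd)
    list(activity = ActivityMatrix(vals, NULL, "classification"),
         fingerprints = fpsKept, truth = truth)
  })
}
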