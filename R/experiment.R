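#' @include sparsify.R
NULL

#' Define a full benchmark run
#'
#' A run spec names a dataset (generator preset or CSV paths), the methods
#' with their hyperparameter sets, the removal models and fraction grid, and
#' the seed-control design (every split seed crossed with every removal
#' seed; the study's control uses 4 x 4 = 16 runs). Validation happens here,
#' before any compute: the tree-ensemble baseline is only valid with the
#' compound removal model.
#'
#' @param dataset preset name (`"pkis_like"`, `"htsfp5_like"`,
#'   `"htsfp10_like"`) or a list `list(activity=, fingerprints=, taskType=)`
#'   of CSV paths.
#' @param datasetArgs overrides for [syntheticPreset()] (e.g. a smaller
#'   `nCompounds`).
#' @param methods named list; names in `"bpmf"`, `"nn"`, `"forest"`. Each
#'   element is a list of hyperparameter sets (each a named list of arguments
#'   for the method's fit function), or a list with elements `hyperparams`
#'   and optional `removalModels` overriding the spec-level removal models
#'   for that method.
#' @param removalModels character vector of removal models applied to every
#'   method that does not override them. The forest method defaults to
#'   `"compound"` only.
#' @param fractions removal-fraction grid, starting at 0.
#' @param splitSeeds,removalSeeds integer vectors; the run grid crosses them.
#' @param testFraction held-out compound fraction (default 0.25, the 3:1
#'   design).
#' @param outputDir directory for the long-form results CSV.
#' @param globalSeed seed from which per-cell method seeds are derived.
#' @return validated list of class `RunSpec`.
#' @export
runSpec <- function(dataset, datasetArgs = list(),
                    methods = list(bpmf = list(list())),
                    removalModels = "label",
                    fractions = c(0, 0.25, 0.5, 0.75, 0.9),
                    splitSeeds = 1L, removalSeeds = 1L,
                    testFraction = 0.25, outputDir = tempfile("mtrun"),
                    globalSeed = 1L) {
  if (!is.list(methods) || is.null(names(methods)) || any(names(methods) == ""))
    stopfmt("'methods' must be a named list")
  bad <- setdiff(names(methods), c("bpmf", "nn", "forest"))
  if (length(bad)) stopfmt("unknown method(s): %s", paste(bad, collapse = ", "))
  if (!all(removalModels %in% c("label", "compound", "assay")))
    stopfmt("removal models must be label/compound/assay")
  if (fractions[1L] != 0 || is.unsorted(fractions, strictly = TRUE))
    stopfmt("fractions must start at 0 and increase strictly")
  methods <- lapply(stats::setNames(names(methods), names(methods)), function(nm) {
    entry <- methods[[nm]]
    if (!is.null(entry$hyperparams)) {
      hp <- entry$hyperparams
      rm_ <- entry$removalModels
    } else {
      hp <- entry
      rm_ <- NULL
    }
    if (length(hp) == 0L) hp <- list(list())
    if (is.null(rm_)) rm_ <- if (nm == "forest") "compound" else removalModels
    if (nm == "forest" && !all(rm_ == "compound"))
      stopfmt("the forest baseline is only valid with the compound removal model")
    if (!all(rm_ %in% removalModels) && !identical(rm_, "compound"))
      stopfmt("method '%s' requests removal models outside the spec", nm)
    list(hyperparams = hp, removalModels = rm_)
  })
  structure(list(dataset = dataset, datasetArgs = datasetArgs,
                 methods = methods, removalModels = removalModels,
                 fractions = fractions,
                 splitSeeds = as.integer(splitSeeds),
                 removalSeeds = as.integer(removalSeeds),
                 testFraction = testFraction, outputDir = outputDir,
                 globalSeed = as.integer(globalSeed)),
            class = "RunSpec")
}

#' Read a run spec from a YAML file
#'
#' The YAML keys mirror the [runSpec()] arguments.
#'
#' @param path YAML file.
#' @return a `RunSpec`.
#' @export
readRunSpec <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runSpec))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stopfmt("unknown run-spec field(s): %s", paste(extra, collapse = ", "))
  do.call(runSpec, y)
}

# Materialize the dataset a spec refers to.
loadDataset <- function(spec) {
  ds <- spec$dataset
  if (is.character(ds) && length(ds) == 1L) {
    cfg <- do.call(syntheticPreset, c(list(name = ds), spec$datasetArgs,
                                      list(seed = spec$globalSeed)))
    out <- if (is.null(cfg$targetActiveRatios)) genRegressionMatrix(cfg)
           else genClassificationMatrix(cfg)
    list(activity = out$activity, fingerprints = out$fingerprints,
         name = ds)
  } else {
    act <- readActivityCsv(ds$activity, taskType = ds$taskType)
    list(activity = act, fingerprints = readFingerprintCsv(ds$fingerprints),
         name = "csv")
  }
}

# Fit + predict one grid cell; returns a prediction matrix aligned with test.
fitPredictCell <- function(method, hyper, train, fpsTrain, test, fpsTest,
                           seed) {
  taskClass <- train@taskType == "classification"
  if (method == "bpmf") {
    trace <- do.call(bpmfFit, c(list(train = train, fps = fpsTrain,
                                     seed = seed), hyper))
    if (taskClass) predictClass(trace, fpsTest, assays = assayIds(train))
    else predictActivity(trace, fpsTest, assays = assayIds(train))
  } else if (method == "nn") {
    net <- do.call(nnFit, c(list(train = train, fps = fpsTrain, seed = seed),
                            hyper))
    predictActivityNet(net, fpsTest,
                       type = if (taskClass) "class" else "response")
  } else if (method == "forest") {
    model <- do.call(forestFit, c(list(train = train, fps = fpsTrain,
                                       seed = seed), hyper))
    predictActivityForest(model, fpsTest,
                          type = if (taskClass) "class" else "response")
  } else stopfmt("unknown method '%s'", method)
}

scoreKeyCols <- c("dataset", "method", "removal_model", "hyperparameter_set",
                  "split_seed", "removal_seed", "fraction")

#' Execute a benchmark run
#'
#' For every cell of the (method x hyperparameter set x removal model x
#' fraction x split seed x removal seed) grid: split compounds 3:1, sparsify
#' the training matrix, fit, predict the untouched test set (evaluation is
#' restricted to surviving assays under assay removal), score per assay, and
#' append to the long-form results CSV in `spec$outputDir`. Cells whose
#' sparsified training matrix has assays (or compounds) without any label are
#' recorded as status rows rather than crashing the run. Already-present
#' cells are skipped, so an interrupted run resumes, and re-running a
#' completed spec appends nothing. Deterministic given the spec seeds.
#'
#' @param spec a [runSpec()].
#' @param verbose print one line per cell.
#' @return the results data.frame, invisibly; the CSV lives at
#'   `file.path(spec$outputDir, "results.csv")`.
#' @export
runExperiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "RunSpec"))
  dir.create(spec$outputDir, showWarnings = FALSE, recursive = TRUE)
  resPath <- file.path(spec$outputDir, "results.csv")
  existing <- if (file.exists(resPath)) {
    utils::read.csv(resPath, stringsAsFactors = FALSE)
  } else NULL
  doneKeys <- if (!is.null(existing)) {
    unique(do.call(paste, c(existing[scoreKeyCols], sep = "|")))
  } else character(0)

  data <- loadDataset(spec)
  cellIdx <- 0L
  for (splitSeed in spec$splitSeeds) {
    split <- trainTestSplit(data$activity, testFraction = spec$testFraction,
                            seed = splitSeed)
    trainIdx <- match(compoundIds(split@train), compoundIds(data$fingerprints))
    testIdx <- match(compoundIds(split@test), compoundIds(data$fingerprints))
    fpsTrain <- FingerprintSet(fingerprintBits(data$fingerprints)[trainIdx, , drop = FALSE])
    fpsTest <- FingerprintSet(fingerprintBits(data$fingerprints)[testIdx, , drop = FALSE])
    for (method in names(spec$methods)) {
      mSpec <- spec$methods[[method]]
      trainBase <- split@train
      if (method == "forest" && !all(observedMask(trainBase)))
        trainBase <- imputeAssayMean(trainBase)
      for (hpIdx in seq_along(mSpec$hyperparams)) {
        hyper <- mSpec$hyperparams[[hpIdx]]
        for (rmModel in mSpec$removalModels) {
          for (removalSeed in spec$removalSeeds) {
            for (fIdx in seq_along(spec$fractions)) {
              frac <- spec$fractions[fIdx]
              cellIdx <- cellIdx + 1L
              key <- paste(data$name, method, rmModel, hpIdx, splitSeed,
                           removalSeed, frac, sep = "|")
              if (key %in% doneKeys) next
              rows <- runOneCell(data$name, method, hyper, hpIdx, rmModel,
                                 frac, splitSeed, removalSeed, trainBase,
                                 fpsTrain, split@test, fpsTest,
                                 deriveSeed(spec$globalSeed, cellIdx))
              if (verbose)
                message(sprintf("[%s %s %s f=%.3f s=%d r=%d] %s",
                                method, rmModel, hpIdx, frac, splitSeed,
                                removalSeed, rows$status[1L]))
              utils::write.table(rows, resPath, sep = ",", append = file.exists(resPath),
                                 col.names = !file.exists(resPath),
                                 row.names = FALSE, qmethod = "double")
            }
          }
        }
      }
    }
  }
  results <- utils::read.csv(resPath, stringsAsFactors = FALSE)
  # canonical order so identical specs produce byte-identical files
  ord <- do.call(order, unname(results[c(scoreKeyCols, "assay_id", "metric")]))
  results <- results[ord, , drop = FALSE]
  utils::write.csv(results, resPath, row.names = FALSE, quote = FALSE)
  invisible(results)
}

runOneCell <- function(dsName, method, hyper, hpIdx, rmModel, frac,
                       splitSeed, removalSeed, trainBase, fpsTrain, test,
                       fpsTest, seed) {
  statusRow <- function(status) {
    data.frame(dataset = dsName, method = method, removal_model = rmModel,
               hyperparameter_set = hpIdx, split_seed = splitSeed,
               removal_seed = removalSeed, fraction = frac,
               assay_id = NA_character_, metric = NA_character_,
               value = NA_real_, status = status, stringsAsFactors = FALSE)
  }
  sparse <- tryCatch(applyRemoval(trainBase, rmModel, frac, removalSeed),
                     error = function(e) e)
  if (inherits(sparse, "error")) return(statusRow("removal_failed"))
  audit <- auditEmpty(sparse)
  if (length(audit$emptyAssays)) return(statusRow("empty_assay"))
  if (method == "bpmf" && length(audit$emptyCompounds))
    return(statusRow("empty_compound"))
  fpsTrainUsed <- FingerprintSet(
    fingerprintBits(fpsTrain)[compoundIds(sparse), , drop = FALSE])
  testUsed <- test
  if (rmModel == "assay") {
    keepJ <- match(assayIds(sparse), assayIds(test))
    testUsed <- subsetActivity(test, j = keepJ)
  }
  pred <- tryCatch(
    fitPredictCell(method, hyper, sparse, fpsTrainUsed, testUsed, fpsTest,
                   seed),
    error = function(e) e)
  if (inherits(pred, "error")) return(statusRow("fit_failed"))
  scores <- scorePredictions(testUsed, pred)
  metricCols <- setdiff(names(scores), c("assay_id", "n", "tp", "tn", "fp", "fn"))
  long <- do.call(rbind, lapply(metricCols, function(mc) {
    data.frame(dataset = dsName, method = method, removal_model = rmModel,
               hyperparameter_set = hpIdx, split_seed = splitSeed,
               removal_seed = removalSeed, fraction = frac,
               assay_id = scores$assay_id, metric = mc,
               value = scores[[mc]], status = "ok", stringsAsFactors = FALSE)
  }))
  long
}

#' Progression curves and degradation summary from a results store
#'
#' Builds one median-across-assays curve per (method, removal model,
#' hyperparameter set) series, their pointwise average per (method, removal
#' model), and a knee table giving the first fraction at which each series
#' degrades by `relChange` relative to its complete-data model.
#'
#' @param results long-form results data.frame from [runExperiment()] (or its
#'   CSV re-read).
#' @param metric metric to report (default `"rmsd"` for regression results,
#'   use `"mcc"` for classification).
#' @param relChange relative degradation defining the knee (default 0.10).
#' @return list with `curves`, `average` and `knees` data.frames.
#' @export
reportCurves <- function(results, metric = "rmsd", relChange = 0.10) {
  ok <- results[results$status == "ok" & results$metric == metric, ]
  if (nrow(ok) == 0L) stopfmt("no successful rows for metric '%s'", metric)
  series <- unique(ok[c("method", "removal_model", "hyperparameter_set")])
  curves <- list(); knees <- list()
  for (i in seq_len(nrow(series))) {
    sel <- ok$method == series$method[i] &
      ok$removal_model == series$removal_model[i] &
      ok$hyperparameter_set == series$hyperparameter_set[i]
    sub <- ok[sel, ]
    sub$value <- as.numeric(sub$value)
    agg <- stats::aggregate(value ~ fraction + assay_id, sub, stats::median)
    names(agg)[3L] <- metric
    curve <- aggregateScores(agg, metric, method = series$method[i],
                             removalModel = series$removal_model[i])
    curve$hyperparameter_set <- series$hyperparameter_set[i]
    curves[[i]] <- curve
    knees[[i]] <- data.frame(series[i, , drop = FALSE],
                             knee_fraction = thresholdCrossing(curve, relChange))
  }
  curves <- do.call(rbind, curves)
  avg <- stats::aggregate(cbind(median, relative) ~ fraction + method +
                            removal_model + metric, curves, mean)
  list(curves = curves, average = avg,
       knees = do.call(rbind, knees))
}
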