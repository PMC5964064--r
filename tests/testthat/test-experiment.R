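# Shared tiny CSV-backed dataset so experiment tests avoid regeneration.
expDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- smallDataset(n = 32, m = 4, seed = 11)
      dir <- tempfile("expdata")
      dir.create(dir)
      actPath <- file.path(dir, "activity.csv")
      fpPath <- file.path(dir, "fingerprints.csv")
      writeActivityCsv(dat$activity, actPath)
      writeFingerprintCsv(dat$fingerprints, fpPath)
      cache <<- list(activity = actPath, fingerprints = fpPath,
                     taskType = "regression")
    }
    cache
  }
})

fastBpmf <- list(list(latentDim = 2L, nSamples = 6L, burnIn = 2L))

test_that("invalid specs are rejected before any compute", {
  expect_error(runSpec("pkis_like",
                       methods = list(forest = list(
                         hyperparams = list(list()),
                         removalModels = "label"))),
               "compound removal")
  expect_error(runSpec("pkis_like", methods = list(gbm = list(list()))),
               "unknown method")
  expect_error(runSpec("pkis_like", fractions = c(0.1, 0.5)), "start at 0")
  expect_error(runSpec("pkis_like",
                       methods = list(nn = list(hyperparams = list(list()),
                                                removalModels = "assay")),
                       removalModels = "label"),
               "outside the spec")
})

test_that("the seed-control grid produces one record set per crossed cell", {
  # compound removal keeps the training matrix complete, so every cell is ok
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "compound", fractions = c(0, 0.5),
                  splitSeeds = 1:2, removalSeeds = 1:2, globalSeed = 3)
  res <- runExperiment(spec)
  keys <- unique(res[c("split_seed", "removal_seed", "fraction")])
  expect_equal(nrow(keys), 2 * 2 * 2)
  expect_true(all(res$status == "ok"))
  # every cell scored every test assay on every regression metric
  perCell <- table(paste(res$split_seed, res$removal_seed, res$fraction))
  expect_true(all(perCell == perCell[1]))
  expect_setequal(unique(res$metric), c("rmsd", "mae", "r2", "rho2"))
})

test_that("relative curves are exactly 1 when only fraction 0 is run", {
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "label", fractions = 0,
                  splitSeeds = 1L, removalSeeds = 1L, globalSeed = 5)
  res <- runExperiment(spec)
  rep <- reportCurves(res, metric = "rmsd")
  expect_true(all(rep$curves$relative == 1))
  expect_true(is.na(rep$knees$knee_fraction))
})

test_that("re-running a completed spec appends nothing and resume reproduces the file", {
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "label", fractions = c(0, 0.4, 0.8),
                  splitSeeds = 1L, removalSeeds = 1L, globalSeed = 7)
  runExperiment(spec)
  resPath <- file.path(spec$outputDir, "results.csv")
  original <- readLines(resPath)
  runExperiment(spec)                                   # idempotent
  expect_identical(readLines(resPath), original)

  res <- utils::read.csv(resPath, stringsAsFactors = FALSE)
  truncated <- res[res$fraction != 0.4, ]
  utils::write.csv(truncated, resPath, row.names = FALSE, quote = FALSE)
  runExperiment(spec)                                   # recompute one fraction
  expect_identical(readLines(resPath), original)
})

test_that("a removal fraction that empties assays yields status rows, not a crash", {
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "label", fractions = c(0, 0.99),
                  splitSeeds = 1L, removalSeeds = 1L, globalSeed = 9)
  res <- runExperiment(spec)
  hi <- res[res$fraction == 0.99, ]
  expect_equal(unique(hi$status), "empty_assay")
  expect_true(all(is.na(hi$value)))
  expect_true(all(res$status[res$fraction == 0] == "ok"))
  rep <- reportCurves(res, metric = "rmsd")             # drops status rows
  expect_equal(unique(rep$curves$fraction), 0)
})

test_that("assay removal restricts evaluation to surviving assays", {
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "assay", fractions = c(0, 0.5),
                  splitSeeds = 1L, removalSeeds = 1L, globalSeed = 13)
  res <- runExperiment(spec)
  ok <- res[res$status == "ok", ]
  nAssay0 <- length(unique(ok$assay_id[ok$fraction == 0]))
  nAssay5 <- length(unique(ok$assay_id[ok$fraction == 0.5]))
  expect_equal(nAssay0, 4L)
  expect_equal(nAssay5, 2L)
})

test_that("the per-(method, removal) average curve equals the single series when only one exists", {
  spec <- runSpec(expDataset(), methods = list(bpmf = fastBpmf),
                  removalModels = "label", fractions = c(0, 0.5),
                  splitSeeds = 1L, removalSeeds = 1L, globalSeed = 15)
  rep <- reportCurves(runExperiment(spec), metric = "rmsd")
  merged <- merge(rep$curves, rep$average,
                  by = c("fraction", "method", "removal_model", "metric"))
  expect_equal(merged$median.x, merged$median.y)
  expect_equal(merged$relative.x, merged$relative.y)
})

test_that("run specs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "dataset: pkis_like",
    "datasetArgs:",
    "  nCompounds: 50",
    "  nAssays: 6",
    "removalModels: label",
    "fractions: [0.0, 0.5]",
    "splitSeeds: [1, 2]",
    "removalSeeds: 1",
    "globalSeed: 4"), path)
  spec <- readRunSpec(path)
  expect_s3_class(spec, "RunSpec")
  expect_equal(spec$fractions, c(0, 0.5))
  expect_equal(spec$splitSeeds, 1:2)
  expect_equal(spec$datasetArgs$nCompounds, 50)
  writeLines(c("dataset: pkis_like", "bogus: 1"), path)
  expect_error(readRunSpec(path), "bogus")
})
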