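test_that("iterative stratification partitions and balances labels", {
  ds <- generateCohort(defaultSyntheticConfig(n = 200L, seed = 2L))
  f <- stratifiedMultilabelFolds(ds, 5, seed = 1)
  # exact partition
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 200L)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  # per-fold label counts near the proportional share
  Y <- labelMatrix(ds)
  for (l in colnames(Y)) {
    perfold <- tapply(Y[, l], f, sum)
    expect_true(all(abs(perfold - sum(Y[, l]) / 5) <= 2),
                info = paste("label", l))
  }
  # determinism
  expect_identical(f, stratifiedMultilabelFolds(ds, 5, seed = 1))
  expect_error(stratifiedMultilabelFolds(ds, 300, seed = 1), "exceed")
})

test_that("label-free instances spread to the smallest folds", {
  Y <- cbind(a = c(rep(1L, 4), rep(0L, 16)),
             b = c(rep(0L, 4), rep(1L, 4), rep(0L, 12)))
  ds <- multiLabelDataset(data.frame(x = 1:20), Y)
  f <- stratifiedMultilabelFolds(ds, 4, seed = 3)
  expect_equal(length(f), 20L)
  expect_true(max(table(f)) - min(table(f)) <= 1)
})

plan2 <- cvPlan(k = 2, repeats = 1, innerK = 2, seed = 5, tune = FALSE)
smallArgs <- list(num.trees = 30L, nTrees = 30L)

test_that("the CV harness bookkeeping is exact", {
  ds <- generateCohort(defaultSyntheticConfig(n = 150L, seed = 6L))
  rep1 <- runCvExperiment(ds, "RF-BR", plan2, methodArgs = smallArgs)
  expect_equal(nrow(rep1@folds), 2L)   # k=2, repeats=1 -> 2 evaluations
  # grand mean equals the arithmetic mean of fold metrics
  s <- rep1@summary
  expect_equal(s$mean[s$metric == "hammingLoss"],
               mean(rep1@folds$hammingLoss), tolerance = 1e-12)
  # the two test partitions tile the dataset
  tests <- unlist(lapply(rep1@audit, `[[`, "test"))
  expect_equal(sort(tests), 1:150)
  expect_error(runCvExperiment(ds, "NOPE", plan2), "arg")
})

test_that("a fixed master seed reproduces the report end to end", {
  ds <- generateCohort(defaultSyntheticConfig(n = 120L, seed = 8L))
  r1 <- runCvExperiment(ds, "RF-CC", plan2, methodArgs = smallArgs)
  r2 <- runCvExperiment(ds, "RF-CC", plan2, methodArgs = smallArgs)
  expect_identical(r1@folds, r2@folds)
})

test_that("oversampling touches training partitions only", {
  ds <- generateCohort(defaultSyntheticConfig(n = 150L, seed = 9L))
  planOv <- cvPlan(k = 2, repeats = 1, innerK = 2, seed = 5,
                   oversample = TRUE, tune = FALSE)
  rOff <- runCvExperiment(ds, "MTV-RF", plan2, methodArgs = smallArgs)
  rOn <- runCvExperiment(ds, "MTV-RF", planOv, methodArgs = smallArgs)
  # identical fold seeds -> identical test partitions with the flag on/off
  expect_identical(lapply(rOff@audit, `[[`, "test"),
                   lapply(rOn@audit, `[[`, "test"))
})

test_that("no pipeline stage touches test-partition rows", {
  ds <- generateCohort(defaultSyntheticConfig(n = 150L, seed = 10L))
  planFull <- cvPlan(k = 3, repeats = 2, innerK = 2, seed = 7,
                     oversample = TRUE, tune = TRUE,
                     grids = list(rf = expand.grid(
                       mtry = c("sqrt"), min.node.size = c(5L, 20L),
                       stringsAsFactors = FALSE)))
  r <- runCvExperiment(ds, "RF-BR", planFull, selectK = 5,
                       methodArgs = smallArgs)
  for (rec in r@audit) {
    for (stage in c("imputerRows", "oversampleRows", "selectionRows",
                    "tuningRows")) {
      expect_length(intersect(rec[[stage]], rec$test), 0)
      expect_gt(length(rec[[stage]]), 0)   # the stage did run
    }
  }
})

test_that("the feature curve reproduces the full experiment at k = p", {
  ds <- generateCohort(defaultSyntheticConfig(n = 120L, seed = 12L))
  p <- ncol(features(ds))
  curve <- runFeatureCurve(ds, "RF-BR", ks = c(3L, p), plan2,
                           methodArgs = smallArgs)
  expect_equal(nrow(curve$table), 2L)
  full <- runCvExperiment(ds, "RF-BR", plan2, methodArgs = smallArgs)
  atP <- curve$reports[["RF-BR"]][[as.character(p)]]
  expect_equal(atP@summary$mean, full@summary$mean, tolerance = 1e-12)
  expect_error(runFeatureCurve(ds, "RF-BR", ks = c(5L, 99L), plan2),
               "exceeds")
})
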