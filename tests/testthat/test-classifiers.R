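# Noise-free separable toy: each label is an exact copy of one binary
# feature, so a forest base learner memorizes the rule and all three
# transformation methods must reach training Hamming loss 0.
separable_toy <- function(n = 40) {
  set.seed(8)
  f1 <- rep(c(0, 1), n / 2)
  f2 <- rep(c(0, 0, 1, 1), n / 4)
  multiLabelDataset(data.frame(f1 = f1, f2 = f2, noise = rnorm(n)),
                    cbind(y1 = as.integer(f1), y2 = as.integer(f2)))
}

rf_base <- baseLearner("rf", num.trees = 80)

test_that("all transformation methods memorize noise-free separable data", {
  ds <- separable_toy()
  for (fit in list(fitBR(ds, rf_base, seed = 1),
                   fitCC(ds, rf_base, seed = 1),
                   fitDBR(ds, rf_base, seed = 1))) {
    expect_equal(hammingLoss(ds, predictLabels(fit, ds)), 0)
  }
})

test_that("chain and dependent stages carry the right label features", {
  ds <- separable_toy()
  cc <- fitCC(ds, rf_base, seed = 1)
  # first chain model sees no label features, last sees all predecessors
  expect_false(any(grepl("^\\.lbl_", cc@models[[cc@chainOrder[1]]]$columns)))
  expect_equal(sum(grepl("^\\.lbl_",
                         cc@models[[cc@chainOrder[2]]]$columns)), 1L)
  expect_error(fitCC(ds, rf_base, order = c("y1", "y1")), "permutation")

  dbr <- fitDBR(ds, rf_base, seed = 1)
  for (l in dbr@labelNames) {
    labfeats <- grep("^\\.lbl_", dbr@models[[l]]$columns, value = TRUE)
    expect_false(paste0(".lbl_", l) %in% labfeats)   # never its own label
    expect_equal(length(labfeats), length(dbr@labelNames) - 1L)
  }
})

test_that("BR ignores other labels; CC and DBR depend on them", {
  # y1 is predictable from x only at ~70%; y2 duplicates y1, so label
  # information is genuinely useful for the dependence-aware methods
  set.seed(31)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  y1 <- ifelse(runif(n) < 0.3, 1L - x, x)
  ds <- multiLabelDataset(data.frame(x = x, z = rnorm(n)),
                          cbind(y1 = y1, y2 = y1))
  # edit the OTHER label column (y2) and refit
  set.seed(77)
  dsEdit <- multiLabelDataset(features(ds),
                              cbind(y1 = y1, y2 = rbinom(n, 1, 0.5)))
  newx <- data.frame(x = rep(c(0, 1), 25), z = rnorm(50))

  br1 <- predictLabels(fitBR(ds, rf_base, seed = 2), newx)
  br2 <- predictLabels(fitBR(dsEdit, rf_base, seed = 2), newx)
  expect_identical(br1@predicted[, "y1"], br2@predicted[, "y1"])

  ordRev <- c("y2", "y1")   # y1 last, so its model consumes y2
  cc1 <- fitCC(ds, rf_base, order = ordRev, seed = 2)
  cc2 <- fitCC(dsEdit, rf_base, order = ordRev, seed = 2)
  expect_false(identical(cc1@models[["y1"]]$model$forest,
                         cc2@models[["y1"]]$model$forest))

  dbr1 <- predictLabels(fitDBR(ds, rf_base, seed = 2), ds)
  dbr2 <- predictLabels(fitDBR(dsEdit, rf_base, seed = 2), ds)
  expect_false(identical(dbr1@scores[, "y1"], dbr2@scores[, "y1"]))
})

test_that("constant labels degrade to constant-rate predictors, not failures", {
  set.seed(5)
  ds <- multiLabelDataset(data.frame(x = rnorm(20)),
                          cbind(y1 = rep(1L, 20),
                                y2 = rep(c(0L, 1L), 10)))
  expect_warning(m <- fitBR(ds, rf_base, seed = 3), "constant")
  p <- predictLabels(m, ds)
  expect_true(all(p@predicted[, "y1"] == 1L))   # observed rate 1
  expect_true(all(p@scores[, "y1"] == 1))
})

test_that("prediction matrices respect the >= threshold tie rule", {
  sc <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  pm <- new("PredictionMatrix",
            predicted = matrix(1L, 2, 2, dimnames = dimnames(sc)),
            scores = sc, threshold = 0.5)
  expect_true(validObject(pm))
  expect_error(new("PredictionMatrix",
                   predicted = matrix(0L, 2, 2, dimnames = dimnames(sc)),
                   scores = sc, threshold = 0.5),
               "indicator")
})

test_that("fits and predictions are deterministic and order-invariant", {
  ds <- separable_toy()
  p1 <- predictLabels(fitCC(ds, rf_base, seed = 9), ds)
  p2 <- predictLabels(fitCC(ds, rf_base, seed = 9), ds)
  expect_identical(p1@scores, p2@scores)
  # instance order invariance
  m <- fitDBR(ds, rf_base, seed = 9)
  idx <- rev(seq_len(nInstances(ds)))
  pRev <- predictLabels(m, ds[idx])
  pFwd <- predictLabels(m, ds)
  expect_equal(pRev@scores, pFwd@scores[idx, ], tolerance = 1e-12)
  # prediction columns follow the dataset label order
  expect_identical(colnames(pFwd@predicted), labelSpace(ds))
})

test_that("the SVM base learner plugs into the same contract", {
  ds <- separable_toy()
  m <- fitBR(ds, baseLearner("svm", cost = 10), seed = 1)
  p <- predictLabels(m, ds)
  expect_lt(hammingLoss(ds, p), 0.1)
  expect_true(all(p@scores >= 0 & p@scores <= 1))
})
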