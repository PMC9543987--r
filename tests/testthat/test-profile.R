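test_that("imbalance profile matches direct ratio arithmetic", {
  # occurrence counts (6, 3, 2) -> IRLbl (1, 2, 3), MeanIR 2
  Y <- cbind(a = rep(1:0, c(6, 4)), b = rep(1:0, c(3, 7)),
             c = rep(1:0, c(2, 8)))
  ds <- multiLabelDataset(data.frame(x = 1:10), Y)
  p <- imbalanceProfile(ds)
  expect_equal(unname(p@irlbl), c(1, 2, 3))
  expect_equal(p@meanIR, 2)
  expect_equal(p@cardinality, 11 / 10)
  expect_equal(p@density, p@cardinality / 3)

  # equally frequent labels: all IRLbl 1
  Yb <- cbind(a = rep(1:0, 5), b = rep(0:1, 5))
  expect_equal(unname(imbalanceProfile(
    multiLabelDataset(data.frame(x = 1:10), Yb))@irlbl), c(1, 1))

  # saturation: every instance has every label
  Ys <- matrix(1L, 7, 3, dimnames = list(NULL, c("a", "b", "c")))
  ps <- imbalanceProfile(multiLabelDataset(data.frame(x = 1:7), Ys))
  expect_equal(ps@cardinality, 3)
  expect_equal(ps@density, 1)

  # zero-occurrence label is a named, explicit error
  Y0 <- cbind(a = rep(1L, 5), b = rep(0L, 5))
  expect_error(imbalanceProfile(multiLabelDataset(data.frame(x = 1:5), Y0)),
               "b")
})

test_that("profile agrees with the recount oracle on random datasets", {
  for (s in 1:60) {
    ds <- random_mld(25, 4, seed = s)
    p <- imbalanceProfile(ds)
    o <- oracle_imbalance(labelMatrix(ds))
    expect_equal(p@cardinality, o$cardinality, tolerance = 1e-12)
    expect_equal(p@density, o$density, tolerance = 1e-12)
    expect_equal(unname(p@irlbl), o$irlbl, tolerance = 1e-12)
    expect_equal(p@meanIR, o$meanIR, tolerance = 1e-12)
    expect_equal(min(p@irlbl), 1)
  }
})

test_that("condition-count table conserves counts and stratifies", {
  ds <- random_mld(80, 6, seed = 5)
  cc <- conditionCountTable(ds)
  expect_equal(sum(cc$buckets), 80)
  # every instance with exactly 2 labels -> all mass in bucket "2"
  Y2 <- cbind(a = rep(1L, 6), b = rep(1L, 6), c = rep(0L, 6))
  cc2 <- conditionCountTable(multiLabelDataset(data.frame(x = 1:6), Y2))
  expect_equal(unname(cc2$buckets[["2"]]), 6L)
  expect_equal(sum(cc2$buckets), 6)
  # stratifier percentages sum to 100 within non-empty columns
  dsStr <- multiLabelDataset(
    cbind(features(ds), grp = rep(c("a", "b"), 40)), labelMatrix(ds))
  ccs <- conditionCountTable(dsStr, stratifier = "grp")
  nonEmpty <- colSums(ccs$table) > 0
  expect_true(all(abs(colSums(ccs$percent)[nonEmpty] - 100) < 0.2))
  expect_error(conditionCountTable(ds, stratifier = "nope"), "not found")
})

test_that("published-cells reconstruction reproduces the cohort descriptives", {
  ds <- reconstructPublishedCohort()
  expect_equal(nInstances(ds), 14836L)
  cc <- conditionCountTable(ds, stratifier = "sex")
  expect_equal(as.integer(cc$buckets),
               publishedDescriptives()$n)
  expect_equal(multimorbidityPrevalence(ds),
               (4111 + 2550 + 1163 + 523) / 14836)
})

test_that("co-occurrence matrix equals exhaustive pair counting", {
  # identical columns co-occur perfectly
  Yd <- cbind(a = c(1, 1, 0, 1, 0), b = c(1, 1, 0, 1, 0),
              c = c(0, 1, 1, 0, 0))
  ds <- multiLabelDataset(data.frame(x = 1:5), Yd)
  co <- cooccurrenceMatrix(ds)
  expect_equal(co$conditional["a", "b"], 1)
  expect_equal(co$conditional["b", "a"], 1)
  expect_true(all(diag(co$conditional) == 1))
  # brute-force pair counts on a hand-built dataset
  for (y in colnames(Yd)) for (x in colnames(Yd)) {
    expect_equal(co$conditional[y, x],
                 sum(Yd[, y] & Yd[, x]) / sum(Yd[, x]))
  }
  # marginal split: prevalence = with-co-occurrence + isolated
  expect_equal(co$prevalence, co$withCooccurrence + co$isolated)

  # independent labels: conditional prevalence approximates the marginal
  set.seed(21)
  Yi <- cbind(a = rbinom(6000, 1, 0.5), b = rbinom(6000, 1, 0.3))
  coi <- cooccurrenceMatrix(multiLabelDataset(data.frame(x = 1:6000), Yi))
  expect_lt(abs(coi$conditional["a", "b"] - mean(Yi[, "a"])), 0.03)
})

test_that("multimorbidity prevalence counts instances with >= 2 conditions", {
  Y <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0), c = c(0, 0, 0, 1))
  expect_equal(multimorbidityPrevalence(
    multiLabelDataset(data.frame(x = 1:4), Y)), 0.25)
  expect_equal(multimorbidityPrevalence(
    multiLabelDataset(data.frame(x = 1:2), matrix(1L, 2, 3,
      dimnames = list(NULL, c("a", "b", "c"))))), 1)
})

test_that("ML-ROS clones minority-label carriers and reduces MeanIR", {
  # balanced dataset returns unchanged with a message
  Yb <- cbind(a = rep(1:0, 5), b = rep(0:1, 5))
  dsb <- multiLabelDataset(data.frame(x = 1:10), Yb)
  expect_message(out <- mlrosOversample(dsb, 0.5, seed = 1), "unchanged")
  expect_equal(nInstances(out), 10L)

  # toy with counts (8, 2): clones only carry the rare label
  set.seed(3)
  Yt <- cbind(common = rep(1:0, c(8, 2)), rare = rep(0:1, c(8, 2)))
  dst <- multiLabelDataset(data.frame(x = 1:10), Yt)
  over <- mlrosOversample(dst, 0.5, seed = 4)
  newRows <- which(isClone(over))
  expect_true(length(newRows) > 0)
  expect_true(all(labelMatrix(over)[newRows, "rare"] == 1L))
  expect_gt(sum(labelMatrix(over)[, "rare"]), 2)
  # original instances retained verbatim
  expect_identical(labelMatrix(over)[1:10, ], Yt)

  # reproducible given a seed
  again <- mlrosOversample(dst, 0.5, seed = 4)
  expect_identical(labelMatrix(again), labelMatrix(over))

  # MeanIR never increases; n bounded by the clone budget
  for (s in 1:100) {
    ds <- random_mld(40, 4, seed = 4000 + s)
    before <- imbalanceProfile(ds)@meanIR
    o <- mlrosOversample(ds, 0.25, seed = s)
    expect_lte(imbalanceProfile(o)@meanIR, before + 1e-12)
    expect_lte(nInstances(o), 40L + ceiling(0.25 * 40))
    expect_gte(nInstances(o), 40L)
  }
})
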