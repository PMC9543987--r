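test_that("CSV loading enforces the analytic-sample rule and round-trips", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(age = c(40, 50, 60, NA, 45, 55),
                   sex = c("m", "f", "f", "m", NA, "f"),
                   d1 = c(1, 0, 1, 0, 1, 0),
                   d2 = c(0, 0, 1, 1, 0, 1))
  write.csv(df, tmp, row.names = FALSE, na = "")
  ds <- loadDataset(tmp, c("d1", "d2"))
  expect_equal(nInstances(ds), 6L)
  expect_equal(labelSpace(ds), c("d1", "d2"))
  expect_equal(attr(ds, "dropped"), 0L)
  expect_true(is.na(features(ds)$age[4]))

  # a row with a missing label cell is dropped and reported
  df2 <- df; df2$d2[3] <- NA
  write.csv(df2, tmp, row.names = FALSE, na = "")
  ds2 <- loadDataset(tmp, c("d1", "d2"))
  expect_equal(nInstances(ds2), 5L)
  expect_equal(attr(ds2, "dropped"), 1L)

  # write/read round trip preserves labels and missingness exactly
  out <- tempfile(fileext = ".csv")
  writeDatasetCsv(ds, out)
  ds3 <- loadDataset(out, c("d1", "d2"))
  expect_identical(labelMatrix(ds3), labelMatrix(ds))
  expect_identical(is.na(features(ds3)$age), is.na(features(ds)$age))

  # errors: absent column, non-binary value
  expect_error(loadDataset(tmp, c("d1", "nope")), "nope")
  df3 <- df; df3$d1[2] <- 2
  write.csv(df3, tmp, row.names = FALSE, na = "")
  expect_error(loadDataset(tmp, c("d1", "d2")), "non-binary")
})

test_that("dataset validity rejects malformed inputs", {
  X <- data.frame(a = 1:3)
  expect_error(multiLabelDataset(X, cbind(y1 = c(0, 1, 2), y2 = 0:2)))
  expect_error(multiLabelDataset(X, cbind(y1 = c(0, NA, 1), y2 = c(1, 0, 1))))
  expect_error(multiLabelDataset(X, cbind(y1 = 0:1 == 0)[, 1, drop = FALSE]))
  expect_error(multiLabelDataset(data.frame(y1 = 1:3),
                                 cbind(y1 = c(0, 1, 1), y2 = c(1, 0, 1))),
               "disjoint")
})

test_that("imputer learns median/mode on the reference rows only", {
  ds <- multiLabelDataset(
    data.frame(num = c(1, 3, NA, 100, 200),
               cat = c("a", "a", "b", NA, "c")),
    cbind(y1 = c(0, 1, 1, 0, 1), y2 = c(1, 0, 1, 0, 0)))
  st <- fitImputer(ds, rows = 1:3)
  expect_equal(st@fills$num, 2)       # median of {1, 3}
  expect_equal(st@fills$cat, "a")     # mode of {a, a, b}

  filled <- applyImputer(ds, st)
  expect_equal(features(filled)$num, c(1, 3, 2, 100, 200))
  expect_equal(as.character(features(filled)$cat),
               c("a", "a", "b", "a", "c"))
  # idempotence
  twice <- applyImputer(filled, st)
  expect_identical(features(twice), features(filled))
  # labels untouched
  expect_identical(labelMatrix(filled), labelMatrix(ds))
  expect_error(fitImputer(ds, rows = integer(0)), "empty")
  # all-missing feature falls back with a warning
  ds2 <- multiLabelDataset(data.frame(v = c(NA_real_, NA_real_)),
                           cbind(y1 = c(0, 1), y2 = c(1, 0)))
  expect_warning(st2 <- fitImputer(ds2), "entirely missing")
  expect_equal(st2@fills$v, 0)
})

test_that("one-hot encoding drops the reference level and maps back", {
  ds <- multiLabelDataset(
    data.frame(num = c(1, 2, 3, 4),
               cat = factor(c("a", "b", "c", "a"))),
    cbind(y1 = c(0, 1, 0, 1), y2 = c(1, 1, 0, 0)))
  enc <- encodeFeatures(ds, "onehot")
  expect_equal(ncol(enc$matrix), 3L)  # num + 2 indicators (3 levels - ref)
  expect_equal(nrow(enc$matrix), 4L)
  expect_equal(enc$matrix[, "num"], c(1, 2, 3, 4))

  # numeric-only dataset encodes to itself
  dsn <- multiLabelDataset(data.frame(a = c(1, 2), b = c(3, 4)),
                           cbind(y1 = c(0, 1), y2 = c(1, 0)))
  expect_equal(unname(encodeFeatures(dsn, "onehot")$matrix),
               unname(as.matrix(features(dsn))))

  # importance aggregation: encoded-column sums return to source features
  vals <- setNames(c(0.5, 0.2, 0.3), colnames(enc$matrix))
  agg <- aggregateToFeatures(vals, enc$map)
  expect_equal(agg[["num"]], 0.5)
  expect_equal(agg[["cat"]], 0.5)

  # unseen categories become all-zero indicators, with a warning
  ds2 <- multiLabelDataset(data.frame(num = 1, cat = "zz"),
                           cbind(y1 = 0L, y2 = 1L))
  expect_warning(enc2 <- encodeFeatures(ds2, "onehot",
                                        levelsMap = enc$levels), "unseen")
  expect_equal(sum(enc2$matrix[1, -1]), 0)

  # encoding requires imputed features
  dsm <- multiLabelDataset(data.frame(num = c(1, NA)),
                           cbind(y1 = c(0, 1), y2 = c(1, 0)))
  expect_error(encodeFeatures(dsm, "onehot"), "missing")
})

test_that("generator cohorts survive a CSV round trip byte-identically", {
  ds <- generateCohort(defaultSyntheticConfig(n = 120L, seed = 11L))
  tmp <- tempfile(fileext = ".csv")
  writeDatasetCsv(ds, tmp)
  back <- loadDataset(tmp, labelSpace(ds))
  expect_identical(labelMatrix(back), labelMatrix(ds))
  expect_equal(attr(back, "dropped"), 0L)
  expect_identical(is.na(features(back)), is.na(features(ds)))
})
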