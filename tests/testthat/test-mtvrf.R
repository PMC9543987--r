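test_that("composite Gini score matches hand arithmetic", {
  # split perfectly separating label 1 while label 2's distribution is the
  # same in both children, uniform weights: score = w1 * 1 = 0.5
  Y <- cbind(y1 = c(1, 1, 1, 0, 0, 0), y2 = c(1, 0, 1, 1, 0, 1))
  expect_equal(compositeGiniScore(Y, left = 1:3), 0.5)
  # a split changing no label distribution scores 0
  Yc <- cbind(y1 = rep(c(1, 0), 4), y2 = rep(c(0, 1), 4))
  expect_equal(compositeGiniScore(Yc, left = c(1, 2, 5, 6)), 0, tolerance = 1e-12)
  # labels pure at the parent contribute 0
  Yp <- cbind(y1 = rep(1L, 6), y2 = c(1, 1, 1, 0, 0, 0))
  expect_equal(compositeGiniScore(Yp, left = 1:3), 0.5)
  expect_error(compositeGiniScore(Y, left = 1:6), "nonempty")
})

test_that("composite score agrees with the brute-force oracle", {
  for (s in 1:40) {
    Y <- random_binary(14, 3, seed = 1200 + s)
    left <- sample(14, sample(2:12, 1))
    set.seed(s)
    w <- runif(3); w <- w / sum(w)
    expect_equal(compositeGiniScore(Y, left, w),
                 oracle_gini_score(Y, left, w), tolerance = 1e-12)
  }
  # single-label data with uniform weight: classical normalized Gini decrease
  for (s in 1:20) {
    y <- cbind(y1 = random_binary(12, 1, seed = 3400 + s)[, 1])
    left <- sample(12, 5)
    expect_equal(compositeGiniScore(y, left, weights = 1),
                 oracle_gini_score(y, left, w = 1), tolerance = 1e-12)
  }
})

test_that("the grown root split attains the exhaustive-oracle optimum", {
  set.seed(17)
  for (s in 1:8) {
    n <- 12
    X <- data.frame(a = round(rnorm(n), 1), b = round(runif(n), 1),
                    g = factor(sample(c("u", "v", "w"), n, replace = TRUE)))
    Y <- random_binary(n, 2, seed = 880 + s)
    if (any(colSums(Y) %in% c(0, n))) next
    ds <- multiLabelDataset(X, Y)
    fit <- fitMtvRf(ds, nTrees = 1, mtry = 3, minNodeSize = 1, seed = s)
    tree <- fit@trees[[1]]
    # bootstrap resample defines the node population the root was scored on
    set.seed(s)
    boot <- floor(runif(n) * n) + 1L
    Xb <- X[boot, , drop = FALSE]; Yb <- Y[boot, , drop = FALSE]
    oracle <- oracle_best_split(Xb, Yb)
    if (tree$feature[1] < 0) {
      expect_lte(oracle$score, 1e-12)
      next
    }
    j <- tree$feature[1] + 1L
    nm <- colnames(features(ds))[j]
    left <- if (is.numeric(Xb[[nm]])) {
      which(Xb[[nm]] <= tree$split[1])
    } else {
      lv <- fit@featureInfo$levels[[nm]]
      sel <- lv[bitwAnd(as.integer(tree$split[1]),
                        2^(seq_along(lv) - 1L)) > 0]
      which(as.character(Xb[[nm]]) %in% sel)
    }
    achieved <- oracle_gini_score(Yb, left)
    expect_equal(achieved, oracle$score, tolerance = 1e-10)
  }
})

test_that("a single tree with all features memorizes separable data", {
  set.seed(4)
  f1 <- rep(c(0, 1), 20); f2 <- rep(c(0, 0, 1, 1), 10)
  ds <- multiLabelDataset(data.frame(f1 = f1, f2 = f2),
                          cbind(y1 = as.integer(f1), y2 = as.integer(f2)))
  fit <- fitMtvRf(ds, nTrees = 30, mtry = 2, minNodeSize = 1, seed = 6)
  expect_equal(hammingLoss(ds, predictMtvRf(fit, ds)), 0)
})

test_that("forests are bit-identical under a fixed seed", {
  ds <- random_mld(60, 3, seed = 44, p = 4)
  f1 <- fitMtvRf(ds, nTrees = 20, seed = 12)
  f2 <- fitMtvRf(ds, nTrees = 20, seed = 12)
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@oob, f2@oob)
  expect_false(identical(f1@trees, fitMtvRf(ds, nTrees = 20, seed = 13)@trees))
})

test_that("forest scores are label-leaf averages inside [0, 1]", {
  ds <- random_mld(80, 3, seed = 71, p = 4)
  f1 <- fitMtvRf(ds, nTrees = 1, seed = 3)
  p1 <- predictMtvRf(f1, ds)
  # duplicating the single tree leaves the averaged scores unchanged
  fdup <- f1
  fdup@trees <- c(f1@trees, f1@trees)
  expect_equal(predictMtvRf(fdup, ds)@scores, p1@scores, tolerance = 1e-12)
  f50 <- fitMtvRf(ds, nTrees = 50, seed = 3)
  sc <- predictMtvRf(f50, ds)@scores
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predictMtvRf(f50, features(ds)[, 1:2, drop = FALSE]), "lack")
})

test_that("correlated labels driven by one feature pick it at the root", {
  set.seed(9)
  n <- 150
  x <- rnorm(n); noise <- matrix(rnorm(3 * n), n, 3)
  Y <- cbind(y1 = as.integer(x > 0), y2 = as.integer(x > 0.2))
  ds <- multiLabelDataset(data.frame(x = x, n1 = noise[, 1],
                                     n2 = noise[, 2], n3 = noise[, 3]), Y)
  fit <- fitMtvRf(ds, nTrees = 40, mtry = 4, seed = 2)
  roots <- vapply(fit@trees, function(t) t$feature[1], integer(1))
  expect_gte(mean(roots == 0L), 0.9)   # feature "x" is column 0
})

test_that("permutation importance isolates the driving feature", {
  set.seed(10)
  n <- 250
  x <- rnorm(n)
  ds <- multiLabelDataset(
    data.frame(x = x, u1 = rnorm(n), u2 = rnorm(n)),
    cbind(y1 = as.integer(x + rnorm(n, 0, 0.4) > 0),
          y2 = as.integer(x + rnorm(n, 0, 0.4) > 0.1)))
  fit <- fitMtvRf(ds, nTrees = 80, seed = 5)
  rep1 <- permutationImportance(fit, ds, runs = 15, seed = 6)
  expect_equal(importanceRanking(rep1)[1], "x")
  expect_gt(rep1@importance[["x"]], 0)
  expect_lt(max(abs(rep1@importance[c("u1", "u2")])),
            rep1@importance[["x"]] / 3)
  # reproducible under a fixed seed
  rep2 <- permutationImportance(fit, ds, runs = 15, seed = 6)
  expect_identical(rep1@importance, rep2@importance)
  expect_error(permutationImportance(fit, ds, runs = 0), "runs")
})

test_that("more trees stabilize the predicted scores", {
  ds <- random_mld(120, 3, seed = 55, p = 4)
  probe <- features(ds)[1:10, ]
  spread <- function(nt) {
    sc <- sapply(1:5, function(s)
      predictMtvRf(fitMtvRf(ds, nTrees = nt, seed = 100 + s), probe)@scores[, 1])
    mean(apply(sc, 1, var))
  }
  expect_lt(spread(150), spread(10))
})

test_that("compound-symmetry weighting favours correlated labels", {
  set.seed(66)
  x <- rnorm(100)
  Y <- cbind(a = as.integer(x > 0), b = as.integer(x > 0.1),
             c = rbinom(100, 1, 0.5))
  ds <- multiLabelDataset(data.frame(x = x, z = rnorm(100)), Y)
  f <- fitMtvRf(ds, nTrees = 5, weighting = "cs", seed = 1)
  w <- f@config$weights
  expect_equal(sum(w), 1)
  expect_gt(w[1], w[3])   # label "a" correlates with "b"; "c" with nothing
})
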