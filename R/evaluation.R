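## The experiment harness: multilabel-stratified repeated cross-validation
## with nested hyperparameter tuning, fold-internal imputation, optional
## ML-ROS oversampling of training partitions, and feature-curve runs.
## Every fold records which row indices each stage touched (the audit), so
## leakage-freedom is checkable, not just asserted.

.child_seed <- function(master, a, b = 0L) {
  as.integer((as.numeric(master) + 104729 * a + 7919 * b) %% 2147483647)
}

.METHODS <- c("MTV-RF", "RF-BR", "RF-CC", "RF-DBR",
              "SVM-BR", "SVM-CC", "SVM-DBR")

#' Iterative-stratification fold assignment for multilabel data
#'
#' Assigns instances to k folds so that each label's positives are spread
#' proportionally. Labels are processed from rarest to most frequent; each
#' yet-unassigned instance carrying the current label goes to the fold with
#' the greatest remaining demand for that label (ties: fewest instances,
#' then seeded random). Instances carrying no label are distributed to the
#' smallest folds. The output is an exact partition.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed (same seed, same assignment).
#' @return integer vector of fold ids in 1..k, one per instance.
#' @export
stratifiedMultilabelFolds <- function(dataset, k, seed = 1L) {
  Y <- labelMatrix(dataset)
  n <- nrow(Y)
  if (k > n) stop("k must not exceed the number of instances")
  if (k < 2L) stop("k must be at least 2")
  set.seed(seed)
  cnt <- colSums(Y)
  demand <- matrix(rep(cnt / k, each = k), nrow = k)
  fold <- rep(NA_integer_, n)
  size <- integer(k)
  for (l in order(cnt)) {                 # rarest label first
    idx <- which(Y[, l] == 1L & is.na(fold))
    if (length(idx) > 1L) idx <- sample(idx)
    for (i in idx) {
      best <- which(demand[, l] == max(demand[, l]))
      if (length(best) > 1L)
        best <- best[size[best] == min(size[best])]
      f <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
      fold[i] <- f
      size[f] <- size[f] + 1L
      pos <- which(Y[i, ] == 1L)
      demand[f, pos] <- demand[f, pos] - 1
    }
  }
  free <- which(is.na(fold))
  if (length(free) > 1L) free <- sample(free)
  for (i in free) {
    f <- which.min(size)
    fold[i] <- f
    size[f] <- size[f] + 1L
  }
  fold
}

#' Build a cross-validation plan
#'
#' @param k outer folds (default 10).
#' @param repeats repetitions of the outer split (default 5).
#' @param innerK folds of the nested tuning loop (default 3).
#' @param seed master seed; per-repeat and per-fold child seeds are derived
#'   from it deterministically.
#' @param oversample ML-ROS the training partitions (default FALSE).
#' @param oversampleBudget clone budget as a fraction of the training
#'   partition size (default 0.25).
#' @param imputeMode `"train"` (fit the imputer on the training partition
#'   and apply it to both partitions, the default) or `"separate"` (fit on
#'   each partition independently).
#' @param tune run the inner tuning loop (default TRUE).
#' @param grids per-learner hyperparameter grids; see [defaultGrids()].
#' @return A [CVPlan-class].
#' @export
cvPlan <- function(k = 10L, repeats = 5L, innerK = 3L, seed = 1L,
                   oversample = FALSE, oversampleBudget = 0.25,
                   imputeMode = c("train", "separate"), tune = TRUE,
                   grids = defaultGrids()) {
  imputeMode <- match.arg(imputeMode)
  stopifnot(k >= 2L, innerK >= 2L, repeats >= 1L)
  new("CVPlan", k = as.integer(k), repeats = as.integer(repeats),
      innerK = as.integer(innerK), seed = as.integer(seed),
      oversample = oversample, oversampleBudget = oversampleBudget,
      imputeMode = imputeMode, tune = tune, grids = grids)
}

#' Default hyperparameter grids for the nested tuning loop
#'
#' Small standard grids: forest-type learners over
#' `mtry in {ceiling(sqrt(p)), ceiling(p/3)}` and
#' `min node size in {5, 20}`; margin-type learners over
#' `cost in {0.1, 1, 10}` and `gamma in {1/p, 4/p}`. Selection is by inner
#' cross-validated Hamming loss.
#'
#' @return named list of grids for `rf`, `svm` and `mtvrf` learners.
#' @export
defaultGrids <- function() {
  list(rf = expand.grid(mtry = c("sqrt", "third"),
                        min.node.size = c(5L, 20L),
                        stringsAsFactors = FALSE),
       svm = expand.grid(cost = c(0.1, 1, 10),
                         gamma = c("inv_p", "inv_p4"),
                         stringsAsFactors = FALSE),
       mtvrf = expand.grid(mtry = c("sqrt", "third"),
                           minNodeSize = c(5L, 20L),
                           stringsAsFactors = FALSE))
}

.resolve_mtry <- function(code, p) {
  if (is.numeric(code)) return(as.integer(code))
  switch(code, sqrt = max(1L, ceiling(sqrt(p))),
         third = max(1L, ceiling(p / 3)),
         as.integer(code))
}

.resolve_gamma <- function(code, p) {
  if (is.numeric(code)) return(code)
  switch(code, inv_p = 1 / p, inv_p4 = 4 / p, as.numeric(code))
}

.restrict_features <- function(ds, feats) {
  # keep the dataset's own column order so that selecting all features is
  # the identity operation
  keep <- intersect(colnames(features(ds)), feats)
  multiLabelDataset(features(ds)[, keep, drop = FALSE], labelMatrix(ds),
                    clone = isClone(ds))
}

## learner family of a method id
.method_family <- function(method) {
  if (method == "MTV-RF") "mtvrf" else if (startsWith(method, "RF")) "rf"
  else "svm"
}

## fit a named method on an imputed training dataset with given params
.fit_method <- function(method, trainDs, params, seed, methodArgs) {
  p <- ncol(features(trainDs))
  if (method == "MTV-RF") {
    fitMtvRf(trainDs,
             nTrees = methodArgs$nTrees %||% 100L,
             mtry = .resolve_mtry(params$mtry %||% "sqrt", p),
             minNodeSize = params$minNodeSize %||% 5L,
             weighting = methodArgs$weighting %||% "uniform",
             seed = seed)
  } else {
    fam <- .method_family(method)
    base <- if (fam == "rf")
      baseLearner("rf",
                  num.trees = methodArgs$num.trees %||% 100L,
                  mtry = .resolve_mtry(params$mtry %||% "sqrt", p),
                  min.node.size = params$min.node.size %||% 5L)
    else
      baseLearner("svm",
                  cost = params$cost %||% 1,
                  gamma = .resolve_gamma(params$gamma %||% "inv_p", p))
    kind <- sub("^(RF|SVM)-", "", method)
    switch(kind,
           BR = fitBR(trainDs, base, seed = seed),
           CC = fitCC(trainDs, base, order = methodArgs$chainOrder,
                      seed = seed),
           DBR = fitDBR(trainDs, base, seed = seed))
  }
}

.predict_method <- function(model, ds) {
  if (is(model, "MtvForest")) predictMtvRf(model, ds)
  else predictLabels(model, ds)
}

## inner innerK-fold tuning on the (already imputed, possibly oversampled)
## training partition; returns the winning grid row as a list
.tune_method <- function(method, trainDs, plan, seed, methodArgs) {
  grid <- plan@grids[[.method_family(method)]]
  if (is.null(grid) || nrow(grid) <= 1L)
    return(as.list(if (is.null(grid)) data.frame() else grid[1L, , drop = FALSE]))
  folds <- stratifiedMultilabelFolds(trainDs, plan@innerK,
                                     seed = .child_seed(seed, 17L))
  losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    hl <- numeric(plan@innerK)
    for (f in seq_len(plan@innerK)) {
      tr <- trainDs[folds != f]
      te <- trainDs[folds == f]
      m <- .fit_method(method, tr, params, .child_seed(seed, g, f),
                       methodArgs)
      hl[f] <- hammingLoss(te, .predict_method(m, te))
    }
    losses[g] <- mean(hl)
  }
  as.list(grid[which.min(losses), , drop = FALSE])
}

#' Run a repeated stratified nested cross-validation experiment
#'
#' For each repeat and outer fold: (1) the imputer is fitted per the plan's
#' mode and applied; (2) the training partition only is optionally ML-ROS
#' oversampled; (3) hyperparameters are tuned by inner stratified
#' cross-validation on the training partition (selection by Hamming loss);
#' (4) the model is refitted on the full training partition at the chosen
#' hyperparameters; (5) the untouched test partition is scored with the
#' example-based metrics. Test partitions are never oversampled, never used
#' for tuning and (in `"train"` imputation mode) never touched by imputer
#' fitting.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param method one of `"MTV-RF"`, `"RF-BR"`, `"RF-CC"`, `"RF-DBR"`,
#'   `"SVM-BR"`, `"SVM-CC"`, `"SVM-DBR"`.
#' @param plan a [CVPlan-class].
#' @param selectK optional: restrict each fold to the top-k features by
#'   BR+IG rank. With `rankingMode = "perFold"` (default) the ranking is
#'   recomputed on each training partition; `"global"` uses one ranking
#'   computed on the full dataset (reproduces a single-ranking workflow, at
#'   the price of selection leakage).
#' @param rankingMode `"perFold"` or `"global"`.
#' @param methodArgs list of fixed method arguments (e.g. `num.trees`,
#'   `nTrees`, `chainOrder`).
#' @return An [ExperimentReport-class].
#' @export
runCvExperiment <- function(dataset, method, plan = cvPlan(),
                            selectK = NULL,
                            rankingMode = c("perFold", "global"),
                            methodArgs = list()) {
  rankingMode <- match.arg(rankingMode)
  method <- match.arg(method, .METHODS)
  globalRanking <- NULL
  if (!is.null(selectK) && rankingMode == "global")
    globalRanking <- brIgRank(dataset)
  rows <- list(); audit <- list()
  for (r in seq_len(plan@repeats)) {
    folds <- stratifiedMultilabelFolds(dataset, plan@k,
                                       seed = .child_seed(plan@seed, r))
    for (f in seq_len(plan@k)) {
      fseed <- .child_seed(plan@seed, r, f)
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      trainDs <- dataset[trainIdx]
      testDs <- dataset[testIdx]
      rec <- list(repeatId = r, fold = f, test = testIdx,
                  imputerRows = integer(0), oversampleRows = integer(0),
                  selectionRows = integer(0), tuningRows = integer(0))

      # (0) optional per-fold feature selection on the training partition
      if (!is.null(selectK)) {
        rk <- if (!is.null(globalRanking)) globalRanking else {
          rec$selectionRows <- trainIdx
          brIgRank(trainDs)
        }
        feats <- selectTopK(rk, selectK)
        trainDs <- .restrict_features(trainDs, feats)
        testDs <- .restrict_features(testDs, feats)
      }

      # (1) fold-internal imputation
      if (plan@imputeMode == "train") {
        imp <- fitImputer(trainDs)
        rec$imputerRows <- trainIdx
        trainDs <- applyImputer(trainDs, imp)
        testDs <- applyImputer(testDs, imp)
      } else {
        rec$imputerRows <- trainIdx
        trainDs <- applyImputer(trainDs, fitImputer(trainDs))
        testDs <- applyImputer(testDs, fitImputer(testDs))
      }

      # (2) oversample the training partition only
      if (plan@oversample) {
        rec$oversampleRows <- trainIdx
        trainDs <- mlrosOversample(trainDs, plan@oversampleBudget,
                                   seed = .child_seed(fseed, 3L))
      }

      # (3) nested tuning on the training partition
      params <- if (plan@tune) {
        rec$tuningRows <- trainIdx
        .tune_method(method, trainDs, plan, fseed, methodArgs)
      } else list()

      # (4) final fit and (5) evaluation on the untouched test partition
      model <- .fit_method(method, trainDs, params, fseed, methodArgs)
      rep_ <- multilabelMetrics(testDs, .predict_method(model, testDs))
      rows[[length(rows) + 1L]] <- data.frame(
        repeatId = r, fold = f, t(metricVector(rep_)),
        hyper = paste(names(params), unlist(params), sep = "=",
                      collapse = ";"),
        stringsAsFactors = FALSE)
      audit[[length(audit) + 1L]] <- rec
    }
  }
  foldsDf <- do.call(rbind, rows)
  mets <- c("hammingLoss", "subsetAccuracy", "accuracy", "precision",
            "recall", "fMeasure")
  summaryDf <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(foldsDf[[m]]), numeric(1)),
    sd = vapply(mets, function(m) sd(foldsDf[[m]]), numeric(1)),
    row.names = NULL)
  new("ExperimentReport", method = method, folds = foldsDf,
      summary = summaryDf, audit = audit)
}

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport:", object@method, "over", nrow(object@folds),
      "fold evaluations\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s %.4f (sd %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
})

#' Feature-curve experiment: performance versus number of selected features
#'
#' Runs the cross-validation experiment with the feature space restricted to
#' the top-k BR+IG features, for each k and method.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param methods character vector of method identifiers.
#' @param ks feature-set sizes (default `c(5, 10, 15, 20, 25)`);
#'   `max(ks) <= p`.
#' @param plan a [CVPlan-class].
#' @param rankingMode `"perFold"` (leakage-safe, default) or `"global"`.
#' @param methodArgs as in [runCvExperiment()].
#' @return list with `reports` (nested list, `reports[[method]][[as.character(k)]]`)
#'   and `table` (data.frame of method x k grand means per metric).
#' @export
runFeatureCurve <- function(dataset, methods, ks = c(5L, 10L, 15L, 20L, 25L),
                            plan = cvPlan(),
                            rankingMode = c("perFold", "global"),
                            methodArgs = list()) {
  rankingMode <- match.arg(rankingMode)
  if (max(ks) > ncol(features(dataset)))
    stop("max(ks) exceeds the number of features")
  reports <- list()
  rows <- list()
  for (m in methods) {
    reports[[m]] <- list()
    for (k in ks) {
      rep_ <- runCvExperiment(dataset, m, plan, selectK = k,
                              rankingMode = rankingMode,
                              methodArgs = methodArgs)
      reports[[m]][[as.character(k)]] <- rep_
      s <- rep_@summary
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, k = k,
        t(setNames(s$mean, s$metric)), stringsAsFactors = FALSE)
    }
  }
  list(reports = reports, table = do.call(rbind, rows))
}
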