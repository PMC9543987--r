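## Multivariate random forest: R surface over the compiled tree grower.
## Trees consume raw columns (numeric as-is, categorical as level codes with
## genuine level-subset splits); no one-hot encoding is involved.

.mtv_encode <- function(X, levelsMap = NULL) {
  p <- ncol(X)
  isCat <- logical(p)
  nLevels <- integer(p)
  levelsOut <- list()
  M <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))
  for (j in seq_len(p)) {
    col <- X[[j]]
    nm <- colnames(X)[j]
    if (is.numeric(col)) {
      M[, j] <- as.numeric(col)
    } else {
      lv <- if (!is.null(levelsMap) && !is.null(levelsMap[[nm]]))
        levelsMap[[nm]] else levels(factor(col))
      if (length(lv) > 64L)
        stop("categorical feature '", nm, "' has more than 64 levels")
      code <- match(as.character(col), lv)
      code[is.na(code)] <- 0L  # unseen level: routes to the right child
      M[, j] <- code
      isCat[j] <- TRUE
      nLevels[j] <- length(lv)
      levelsOut[[nm]] <- lv
    }
  }
  list(matrix = M, isCat = isCat, nLevels = nLevels, levels = levelsOut,
       featureNames = colnames(X))
}

#' Composite normalized Gini score of a candidate split
#'
#' Scores a binary partition of a node's instances by
#' `sum_l w_l * dGini_l / Gini_l(parent)`, where `Gini_l = 2 p_l (1 - p_l)`
#' is the per-label Gini impurity at the node and `dGini_l` the impurity
#' decrease induced by the partition. Labels pure at the parent contribute 0.
#' This is the splitting rule that couples the labels inside the
#' multivariate forest.
#'
#' @param Y 0/1 label matrix of the node's instances.
#' @param left logical or integer index selecting the left child's rows; both
#'   children must be nonempty.
#' @param weights per-label weights summing to 1 (default uniform).
#' @return numeric score >= 0.
#' @export
compositeGiniScore <- function(Y, left, weights = NULL) {
  Y <- .as_label_matrix(Y)
  if (is.logical(left)) left <- which(left)
  n <- nrow(Y)
  if (length(left) == 0L || length(left) == n)
    stop("both children must be nonempty")
  if (is.null(weights)) weights <- rep(1 / ncol(Y), ncol(Y))
  stopifnot(length(weights) == ncol(Y))
  g <- function(pos, m) { p <- pos / m; 2 * p * (1 - p) }
  cnt <- colSums(Y)
  nl <- length(left); nr <- n - nl
  posL <- colSums(Y[left, , drop = FALSE])
  giniP <- g(cnt, n)
  dg <- giniP - (nl / n) * g(posL, nl) - (nr / n) * g(cnt - posL, nr)
  active <- giniP > 0
  sum(weights[active] * dg[active] / giniP[active])
}

#' Fit a multivariate random forest
#'
#' Grows `nTrees` trees on bootstrap samples of the instances. At every node,
#' `mtry` features are sampled without replacement and the best candidate
#' split by [compositeGiniScore()] is taken (strictly positive score
#' required; ties go to the first candidate in sampled order). Numeric splits
#' are placed at midpoints between sorted distinct values; categorical splits
#' scan prefix partitions of the levels ordered by weighted positive rate.
#' Growth stops when a node reaches `minNodeSize` instances or no split
#' improves the score. Out-of-bag row indices are stored per tree for
#' [permutationImportance()].
#'
#' @param dataset a [MultiLabelDataset-class] with imputed features (n >= 2).
#' @param nTrees number of trees (default 500).
#' @param mtry features sampled per node (default `ceiling(sqrt(p))`).
#' @param minNodeSize nodes at or below this size become leaves (default 5).
#' @param weighting label-weight structure for the composite score:
#'   `"uniform"` (identity structure, default) or `"cs"`
#'   (compound-symmetry-style: weights proportional to each label's mean
#'   absolute correlation with the other labels).
#' @param weights optional explicit per-label weights (overrides
#'   `weighting`); normalized to sum to 1.
#' @param seed integer seed; fixed seed gives a bit-identical forest.
#' @return An [MtvForest-class].
#' @export
fitMtvRf <- function(dataset, nTrees = 500L, mtry = NULL, minNodeSize = 5L,
                     weighting = c("uniform", "cs"), weights = NULL,
                     seed = 1L) {
  weighting <- match.arg(weighting)
  X <- features(dataset)
  if (anyNA(X)) stop("features contain missing values; impute before fitting")
  if (nInstances(dataset) < 2L) stop("need at least 2 instances")
  stopifnot(nTrees >= 1L)
  Y <- labelMatrix(dataset)
  L <- ncol(Y)
  if (is.null(weights)) {
    if (weighting == "uniform") {
      weights <- rep(1 / L, L)
    } else {
      C <- suppressWarnings(stats::cor(Y))
      C[!is.finite(C)] <- 0
      diag(C) <- NA
      w <- rowMeans(abs(C), na.rm = TRUE)
      if (all(w == 0)) w <- rep(1, L)
      weights <- w / sum(w)
    }
  } else {
    stopifnot(length(weights) == L, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  enc <- .mtv_encode(X)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(enc$matrix))))
  set.seed(seed)
  res <- .mm_grow_forest(enc$matrix, Y, enc$isCat, enc$nLevels, weights,
                         as.integer(nTrees), as.integer(mtry),
                         as.integer(minNodeSize))
  new("MtvForest", trees = res$trees, oob = res$oob,
      config = list(nTrees = as.integer(nTrees), mtry = as.integer(mtry),
                    minNodeSize = as.integer(minNodeSize), weights = weights,
                    weighting = weighting, seed = as.integer(seed),
                    n = nInstances(dataset)),
      featureInfo = enc[c("isCat", "nLevels", "levels", "featureNames")],
      labelNames = colnames(Y))
}

.mtv_design <- function(model, newdata) {
  X <- if (is(newdata, "MultiLabelDataset")) features(newdata) else newdata
  miss <- setdiff(model@featureInfo$featureNames, colnames(X))
  if (length(miss))
    stop("prediction data lack feature(s): ", paste(miss, collapse = ", "))
  X <- X[, model@featureInfo$featureNames, drop = FALSE]
  if (anyNA(X)) stop("features contain missing values; impute before predicting")
  .mtv_encode(X, levelsMap = model@featureInfo$levels)$matrix
}

#' Predict with a multivariate random forest
#'
#' The per-label score of an instance is the mean, over trees, of the
#' terminal node's per-label positive fraction; labels are predicted where
#' the score reaches `threshold`.
#'
#' @param model an [MtvForest-class].
#' @param newdata a [MultiLabelDataset-class] or feature data.frame.
#' @param threshold probability cutoff (default 0.5, ties predict 1).
#' @return A [PredictionMatrix-class] with scores retained.
#' @export
predictMtvRf <- function(model, newdata, threshold = 0.5) {
  M <- .mtv_design(model, newdata)
  scores <- .mm_forest_scores(model@trees, M, model@featureInfo$isCat,
                              length(model@labelNames))
  .new_prediction(scores, threshold, model@labelNames)
}

#' @describeIn predictMtvRf `predict` method delegating to `predictMtvRf`.
#' @param object an [MtvForest-class].
#' @param ... ignored.
#' @export
setMethod("predict", "MtvForest",
          function(object, newdata, threshold = 0.5, ...)
            predictMtvRf(object, newdata, threshold))

setMethod("show", "MtvForest", function(object) {
  cat("MtvForest:", object@config$nTrees, "trees, mtry",
      object@config$mtry, ", min node size", object@config$minNodeSize, "\n")
  cat("  labels:", paste(object@labelNames, collapse = ", "), "\n")
  cat("  label weighting:", object@config$weighting, "\n")
})

#' Permutation variable importance for a multivariate forest
#'
#' For each permutation run and each feature, the feature's values are
#' shuffled among each tree's out-of-bag rows, out-of-bag predictions are
#' recomputed, and the importance contribution is the increase in the
#' multilabel loss (Hamming loss) relative to the intact out-of-bag loss.
#' Contributions are averaged over runs (100 by default).
#'
#' @param model an [MtvForest-class] fitted on `dataset` (out-of-bag indices
#'   must refer to its rows).
#' @param dataset the [MultiLabelDataset-class] the forest was fitted on.
#' @param runs number of permutation runs (default 100).
#' @param loss multilabel loss; only `"hamming"` is implemented.
#' @param seed integer seed for the permutations.
#' @param threshold probability cutoff used to binarize out-of-bag scores.
#' @return An [ImportanceReport-class].
#' @export
permutationImportance <- function(model, dataset, runs = 100L,
                                  loss = "hamming", seed = 1L,
                                  threshold = 0.5) {
  if (runs < 1L) stop("`runs` must be at least 1")
  loss <- match.arg(loss, "hamming")
  if (nInstances(dataset) != model@config$n)
    stop("dataset does not match the one the forest was fitted on")
  M <- .mtv_design(model, dataset)
  set.seed(seed)
  imp <- .mm_perm_importance(model@trees, model@oob, M,
                             labelMatrix(dataset),
                             model@featureInfo$isCat,
                             as.integer(runs), threshold)
  names(imp) <- model@featureInfo$featureNames
  new("ImportanceReport", importance = imp, runs = as.integer(runs),
      loss = loss)
}

setMethod("show", "ImportanceReport", function(object) {
  cat("ImportanceReport (", object@loss, " loss, ", object@runs,
      " runs)\n", sep = "")
  ord <- order(-object@importance)
  print(round(object@importance[ord], 5))
})

#' Rank features of an importance report, descending
#'
#' @param report an [ImportanceReport-class].
#' @return character vector of feature names, most important first (ties
#'   broken lexicographically).
#' @export
importanceRanking <- function(report) {
  v <- report@importance
  names(v)[order(-v, names(v))]
}
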