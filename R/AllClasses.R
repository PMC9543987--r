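#' @import methods
#' @importFrom stats median predict quantile rbinom rnorm runif setNames uniroot var sd plogis rlnorm pnorm qnorm cor
#' @importFrom utils read.csv write.csv head
#' @useDynLib MultiMorbML, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MultiLabelDataset: participants with features and binary condition labels
#'
#' The central container of the package: an ordered collection of participant
#' records, each with a mixed-type feature vector (numeric or categorical,
#' missing values permitted) and a complete binary label vector over a named
#' label space of chronic conditions. Rows with incomplete label information
#' must be excluded before construction (see [loadDataset()]).
#'
#' @slot features data.frame of predictor columns (numeric or factor; NA
#'   allowed). Row order is stable: instance `i` corresponds to label set
#'   `labelMatrix(x)[i, ]`.
#' @slot labelMatrix integer matrix (n x L) with entries exactly 0 or 1 and
#'   column names giving the ordered label space.
#' @slot clone logical vector flagging rows appended as oversampling clones
#'   of original instances (all `FALSE` on construction).
#'
#' @seealso [multiLabelDataset()], [loadDataset()], [imbalanceProfile()]
#' @export
setClass("MultiLabelDataset",
  representation(
    features = "data.frame",
    labelMatrix = "matrix",
    clone = "logical"
  )
)

setValidity("MultiLabelDataset", function(object) {
  Y <- object@labelMatrix
  X <- object@features
  msg <- character()
  if (nrow(Y) < 1L) msg <- c(msg, "dataset must contain at least one instance")
  if (ncol(Y) < 2L) msg <- c(msg, "label space must contain at least 2 labels")
  if (is.null(colnames(Y)) || anyDuplicated(colnames(Y)))
    msg <- c(msg, "label columns must be uniquely named")
  if (anyNA(Y) || !all(Y %in% c(0L, 1L)))
    msg <- c(msg, "label values must be exactly 0 or 1 with no missing entries")
  if (nrow(X) != nrow(Y))
    msg <- c(msg, "feature table and label matrix must have the same number of rows")
  if (ncol(X) > 0L && (is.null(colnames(X)) || anyDuplicated(colnames(X))))
    msg <- c(msg, "feature columns must be uniquely named")
  if (length(intersect(colnames(X), colnames(Y))) > 0L)
    msg <- c(msg, "feature names and label names must be disjoint")
  if (length(object@clone) != nrow(Y))
    msg <- c(msg, "clone flag length must equal the instance count")
  if (length(msg)) msg else TRUE
})

#' PredictionMatrix: per-instance predicted label sets
#'
#' Holds the binary prediction matrix Z (one predicted label set per
#' instance), optionally with the per-label probability scores it was
#' thresholded from. When scores are present the binary matrix equals
#' `score >= threshold` cell by cell.
#'
#' @slot predicted integer matrix (n x L), entries 0/1, label columns in the
#'   order of the dataset the prediction was produced for.
#' @slot scores `NULL`, or a numeric matrix of probabilities in \[0, 1\] with
#'   the same shape as `predicted`.
#' @slot threshold numeric scalar cutoff used to binarize scores.
#' @export
setClass("PredictionMatrix",
  representation(predicted = "matrix", scores = "ANY", threshold = "numeric")
)

setValidity("PredictionMatrix", function(object) {
  P <- object@predicted
  msg <- character()
  if (anyNA(P) || !all(P %in% c(0L, 1L)))
    msg <- c(msg, "predicted entries must be 0/1")
  if (!is.null(object@scores)) {
    S <- object@scores
    if (!is.matrix(S) || any(dim(S) != dim(P)))
      msg <- c(msg, "scores must be a matrix with the shape of `predicted`")
    else {
      if (anyNA(S) || any(S < 0) || any(S > 1))
        msg <- c(msg, "scores must lie in [0, 1]")
      else if (!all((S >= object@threshold) == (P == 1L)))
        msg <- c(msg, "predicted must equal indicator(score >= threshold)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ImputerState: fold-learned fill statistics for missing feature values
#'
#' Stores, per feature, the fill statistic learned from a reference partition:
#' the median for numeric features and the mode for categorical features.
#' Fitted on feature columns only, never on labels; applying it leaves
#' non-missing cells unchanged.
#'
#' @slot fills named list mapping feature name to its fill value.
#' @slot types named character vector, `"numeric"` or `"categorical"`.
#' @export
setClass("ImputerState",
  representation(fills = "list", types = "character")
)

#' ImbalanceProfile: cardinality, density and per-label imbalance
#'
#' Label cardinality LC is the mean number of conditions per participant;
#' label density LD is LC divided by the number of labels; IRLbl(y) is the
#' occurrence count of the most frequent label divided by the count of label
#' y (so the most frequent label has IRLbl 1); MeanIR is the average IRLbl
#' over labels and summarizes the global imbalance level.
#'
#' @slot cardinality numeric scalar, mean labels per instance.
#' @slot density numeric scalar, `cardinality / L`.
#' @slot irlbl named numeric vector of per-label imbalance ratios (all >= 1).
#' @slot meanIR numeric scalar, mean of `irlbl`.
#' @export
setClass("ImbalanceProfile",
  representation(cardinality = "numeric", density = "numeric",
                 irlbl = "numeric", meanIR = "numeric")
)

#' MetricReport: example-based multilabel evaluation metrics
#'
#' @slot hammingLoss,subsetAccuracy,accuracy,precision,recall,fMeasure numeric
#'   proportions in \[0, 1\].
#' @slot nEvaluated integer instance count the metrics were computed over.
#' @seealso [multilabelMetrics()]
#' @export
setClass("MetricReport",
  representation(hammingLoss = "numeric", subsetAccuracy = "numeric",
                 accuracy = "numeric", precision = "numeric",
                 recall = "numeric", fMeasure = "numeric",
                 nEvaluated = "integer")
)

#' FeatureRanking: aggregated information-gain feature scores
#'
#' @slot perLabel numeric matrix (features x labels) of information-gain
#'   scores in bits.
#' @slot aggregate named numeric vector of per-feature aggregated scores.
#' @slot ordering character vector of feature names, descending by aggregate
#'   score (ties broken lexicographically).
#' @slot aggregation character, `"mean"` or `"max"`.
#' @export
setClass("FeatureRanking",
  representation(perLabel = "matrix", aggregate = "numeric",
                 ordering = "character", aggregation = "character")
)

#' TransformationModel: fitted BR / CC / DBR multilabel classifier
#'
#' @slot method character, one of `"BR"`, `"CC"`, `"DBR"`.
#' @slot models list of fitted per-label base learners (for DBR, the second
#'   stage; the internal BR stage lives in `stage1`).
#' @slot stage1 list, the internal binary-relevance stage used by DBR at
#'   prediction time (empty otherwise).
#' @slot chainOrder character permutation of the label space (CC only).
#' @slot threshold numeric probability cutoff.
#' @slot labelNames character, ordered label space.
#' @slot schema list describing the feature columns seen at fit time.
#' @slot base list, the base-learner specification used.
#' @export
setClass("TransformationModel",
  representation(method = "character", models = "list", stage1 = "list",
                 chainOrder = "character", threshold = "numeric",
                 labelNames = "character", schema = "list", base = "list")
)

#' MtvForest: fitted multivariate random forest
#'
#' A forest of multivariate trees grown with the composite normalized Gini
#' splitting rule, which scores a candidate split by the weighted sum over
#' labels of the per-label Gini impurity decrease normalized by the parent
#' impurity of that label.
#'
#' @slot trees list of tree structures (parallel arrays of split features,
#'   thresholds / level masks, child links and per-label leaf fractions).
#' @slot oob list of integer vectors: per-tree out-of-bag row indices.
#' @slot config list of fitting parameters (`nTrees`, `mtry`, `minNodeSize`,
#'   `weights`, `seed`, `weighting`).
#' @slot featureInfo list describing feature columns (names, categorical
#'   flags, level tables).
#' @slot labelNames character, ordered label space.
#' @export
setClass("MtvForest",
  representation(trees = "list", oob = "list", config = "list",
                 featureInfo = "list", labelNames = "character")
)

#' ImportanceReport: permutation variable importance
#'
#' Mean increase in a multilabel loss on out-of-bag predictions when one
#' feature's values are permuted, averaged over repeated permutation runs.
#'
#' @slot importance named numeric vector of per-feature mean loss increases,
#'   sorted in input feature order.
#' @slot runs integer, number of permutation runs averaged.
#' @slot loss character, the multilabel loss used (currently Hamming loss).
#' @export
setClass("ImportanceReport",
  representation(importance = "numeric", runs = "integer", loss = "character")
)

#' SyntheticConfig: parameters of the latent-factor cohort generator
#'
#' @slot n integer cohort size.
#' @slot targets named numeric vector of per-label target prevalences.
#' @slot intercepts named numeric vector of per-label logistic intercepts.
#' @slot loadings numeric matrix (labels x 2): per-label loadings on the
#'   cardio-metabolic and mental latent factors.
#' @slot coefs named list of per-label coefficient vectors over the derived
#'   covariates.
#' @slot missingRate numeric, completely-at-random feature missingness rate.
#' @slot seed integer random seed.
#' @export
setClass("SyntheticConfig",
  representation(n = "integer", targets = "numeric", intercepts = "numeric",
                 loadings = "matrix", coefs = "list",
                 missingRate = "numeric", seed = "integer")
)

#' CVPlan: repeated stratified cross-validation plan
#'
#' @slot k integer outer folds.
#' @slot repeats integer repetitions of the outer split.
#' @slot innerK integer folds of the nested tuning loop.
#' @slot seed integer master seed.
#' @slot oversample logical, ML-ROS the training partitions.
#' @slot oversampleBudget numeric, clone budget as a fraction of n.
#' @slot imputeMode character, `"train"` (fit on training partition, apply to
#'   both) or `"separate"` (fit on each partition independently).
#' @slot tune logical, run the inner tuning loop.
#' @slot grids list of per-learner hyperparameter grids.
#' @export
setClass("CVPlan",
  representation(k = "integer", repeats = "integer", innerK = "integer",
                 seed = "integer", oversample = "logical",
                 oversampleBudget = "numeric", imputeMode = "character",
                 tune = "logical", grids = "list")
)

#' ExperimentReport: aggregated cross-validation results for one method
#'
#' @slot method character method identifier.
#' @slot folds data.frame with one row per repeat x fold and one column per
#'   metric, plus the chosen hyperparameters.
#' @slot summary data.frame of grand means and standard deviations per metric.
#' @slot audit list of per-fold row-index records (which rows each pipeline
#'   stage touched), used to verify that no test-partition information leaks
#'   into imputation, oversampling, selection or tuning.
#' @export
setClass("ExperimentReport",
  representation(method = "character", folds = "data.frame",
                 summary = "data.frame", audit = "list")
)
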