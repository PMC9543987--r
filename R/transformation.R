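## Problem-transformation multilabel classifiers: Binary Relevance (BR),
## Classifier Chain (CC) and Dependent Binary Relevance (DBR) over the
## base-learner contract. Label-valued features are passed to base learners
## as numeric 0/1 columns.

## Build the fit-time design for a base learner: raw imputed columns for
## tree learners, a one-hot matrix for margin learners. Returns the design,
## plus the schema needed to rebuild it at prediction time.
.design_for <- function(dataset, base) {
  X <- features(dataset)
  if (anyNA(X))
    stop("features contain missing values; impute before fitting")
  if (base$needsNumeric) {
    enc <- encodeFeatures(dataset, "onehot")
    list(X = enc$matrix, levels = enc$levels, encoded = TRUE,
         featureNames = colnames(features(dataset)))
  } else {
    lv <- lapply(X, function(c) if (is.factor(c)) levels(c) else NULL)
    lv <- lv[!vapply(lv, is.null, logical(1))]
    list(X = X, levels = lv, encoded = FALSE,
         featureNames = colnames(X))
  }
}

.design_apply <- function(newdata, schema, base) {
  ds <- if (is(newdata, "MultiLabelDataset")) newdata else
    multiLabelDataset(newdata,
                      matrix(0L, nrow(newdata), 2L,
                             dimnames = list(NULL, c(".z1", ".z2"))))
  miss <- setdiff(schema$featureNames, colnames(features(ds)))
  if (length(miss))
    stop("prediction data lack feature(s): ", paste(miss, collapse = ", "))
  X <- features(ds)[, schema$featureNames, drop = FALSE]
  if (anyNA(X))
    stop("features contain missing values; impute before predicting")
  if (schema$encoded) {
    dd <- multiLabelDataset(X, matrix(0L, nrow(X), 2L,
                                      dimnames = list(NULL, c(".z1", ".z2"))))
    encodeFeatures(dd, "onehot", levelsMap = schema$levels)$matrix
  } else {
    for (nm in names(schema$levels))
      X[[nm]] <- factor(as.character(X[[nm]]), levels = schema$levels[[nm]])
    X
  }
}

## Append label columns (numeric 0/1) to a design.
.augment <- function(X, labelValues) {
  if (length(labelValues) == 0L) return(X)
  A <- as.data.frame(lapply(labelValues, as.numeric))
  names(A) <- paste0(".lbl_", names(labelValues))
  if (is.matrix(X)) cbind(X, as.matrix(A)) else cbind(X, A)
}

.new_prediction <- function(scores, threshold, labelNames) {
  colnames(scores) <- labelNames
  pred <- matrix(as.integer(scores >= threshold), nrow(scores),
                 ncol(scores), dimnames = dimnames(scores))
  new("PredictionMatrix", predicted = pred, scores = scores,
      threshold = threshold)
}

#' Fit a Binary Relevance multilabel classifier
#'
#' Trains one independent binary base learner per label; label dependencies
#' are deliberately ignored. No label ever appears in any learner's feature
#' set.
#'
#' @param dataset a [MultiLabelDataset-class] with imputed features.
#' @param base a [baseLearner()] specification.
#' @param seed integer seed; per-label child seeds are derived from it.
#' @param threshold probability cutoff for binarization (ties predict 1).
#' @return A [TransformationModel-class] with `method = "BR"`.
#' @export
fitBR <- function(dataset, base = baseLearner("rf"), seed = 1L,
                  threshold = 0.5) {
  schema <- .design_for(dataset, base)
  Y <- labelMatrix(dataset)
  models <- lapply(seq_len(ncol(Y)), function(l)
    .fit_binary(base, schema$X, Y[, l], seed = seed + l))
  names(models) <- colnames(Y)
  new("TransformationModel", method = "BR", models = models, stage1 = list(),
      chainOrder = character(0), threshold = threshold,
      labelNames = colnames(Y), schema = schema[-1L], base = base)
}

#' Fit a Classifier Chain multilabel classifier
#'
#' Trains per-label binary learners in a fixed chain order; the learner for
#' the k-th label in the chain sees the true values of the preceding k-1
#' labels as additional 0/1 features. At prediction time the chain is walked
#' sequentially, each learner consuming the thresholded predictions of its
#' predecessors.
#'
#' @inheritParams fitBR
#' @param order chain order: a permutation of the label space, or `NULL` for
#'   the dataset's label-column order, or `"random"` for a seeded random
#'   permutation. CC results depend on this choice.
#' @return A [TransformationModel-class] with `method = "CC"`.
#' @export
fitCC <- function(dataset, base = baseLearner("rf"), order = NULL,
                  seed = 1L, threshold = 0.5) {
  Y <- labelMatrix(dataset)
  lbl <- colnames(Y)
  if (is.null(order)) order <- lbl
  else if (identical(order, "random")) {
    set.seed(seed); order <- sample(lbl)
  }
  if (!identical(sort(order), sort(lbl)) || anyDuplicated(order))
    stop("`order` must be a permutation of the label space")
  schema <- .design_for(dataset, base)
  models <- list()
  for (k in seq_along(order)) {
    prev <- order[seq_len(k - 1L)]
    Xk <- .augment(schema$X,
                   setNames(lapply(prev, function(p) Y[, p]), prev))
    models[[order[k]]] <- .fit_binary(base, Xk, Y[, order[k]],
                                      seed = seed + k)
  }
  new("TransformationModel", method = "CC", models = models, stage1 = list(),
      chainOrder = order, threshold = threshold, labelNames = lbl,
      schema = schema[-1L], base = base)
}

#' Fit a Dependent Binary Relevance multilabel classifier
#'
#' Two stages: an internal Binary Relevance stage, and a dependent stage in
#' which the learner for each label sees the true values of all *other*
#' labels as additional 0/1 features (never its own). At prediction time the
#' BR stage estimates the other labels and feeds those estimates to the
#' dependent stage.
#'
#' @inheritParams fitBR
#' @return A [TransformationModel-class] with `method = "DBR"`.
#' @export
fitDBR <- function(dataset, base = baseLearner("rf"), seed = 1L,
                   threshold = 0.5) {
  br <- fitBR(dataset, base, seed = seed, threshold = threshold)
  Y <- labelMatrix(dataset)
  lbl <- colnames(Y)
  schema <- .design_for(dataset, base)
  models <- lapply(seq_along(lbl), function(l) {
    others <- lbl[-l]
    Xl <- .augment(schema$X,
                   setNames(lapply(others, function(p) Y[, p]), others))
    .fit_binary(base, Xl, Y[, l], seed = seed + ncol(Y) + l)
  })
  names(models) <- lbl
  new("TransformationModel", method = "DBR", models = models,
      stage1 = br@models, chainOrder = character(0), threshold = threshold,
      labelNames = lbl, schema = schema[-1L], base = base)
}

#' Predict label sets with a fitted transformation model
#'
#' BR scores each label independently; CC walks the chain feeding thresholded
#' predecessor predictions; DBR runs its internal BR stage and feeds the
#' thresholded estimates of the other labels to the dependent stage.
#' Predictions are invariant to instance order.
#'
#' @param model a [TransformationModel-class].
#' @param newdata a [MultiLabelDataset-class] or feature data.frame with the
#'   fit-time feature columns (imputed).
#' @return A [PredictionMatrix-class] with scores retained.
#' @export
predictLabels <- function(model, newdata) {
  lbl <- model@labelNames
  X <- .design_apply(newdata, model@schema, model@base)
  n <- nrow(X)
  scores <- matrix(NA_real_, n, length(lbl),
                   dimnames = list(NULL, lbl))
  if (model@method == "BR") {
    for (l in lbl) scores[, l] <- .score_binary(model@models[[l]], X)
  } else if (model@method == "CC") {
    hard <- list()
    for (k in seq_along(model@chainOrder)) {
      l <- model@chainOrder[k]
      prev <- model@chainOrder[seq_len(k - 1L)]
      Xk <- .augment(X, hard[prev])
      s <- .score_binary(model@models[[l]], Xk)
      scores[, l] <- s
      hard[[l]] <- as.integer(s >= model@threshold)
    }
  } else {  # DBR
    stage1 <- vapply(lbl, function(l)
      as.integer(.score_binary(model@stage1[[l]], X) >= model@threshold),
      integer(n))
    if (n == 1L) stage1 <- matrix(stage1, nrow = 1L,
                                  dimnames = list(NULL, lbl))
    for (l in lbl) {
      others <- setdiff(lbl, l)
      Xl <- .augment(X, setNames(
        lapply(others, function(p) stage1[, p]), others))
      scores[, l] <- .score_binary(model@models[[l]], Xl)
    }
  }
  .new_prediction(scores, model@threshold, lbl)
}

#' @describeIn predictLabels `predict` method delegating to `predictLabels`.
#' @param object a fitted [TransformationModel-class].
#' @param ... ignored.
#' @export
setMethod("predict", "TransformationModel",
          function(object, newdata, ...) predictLabels(object, newdata))

setMethod("show", "TransformationModel", function(object) {
  cat("TransformationModel (", object@method, "), base learner: ",
      object@base$kind, "\n", sep = "")
  cat("  labels:", paste(object@labelNames, collapse = ", "), "\n")
  if (length(object@chainOrder))
    cat("  chain order:", paste(object@chainOrder, collapse = " -> "), "\n")
  cat("  threshold:", object@threshold, "\n")
})
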