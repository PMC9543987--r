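## Example-based multilabel metrics.
## Truth may be a MultiLabelDataset or a 0/1 matrix; predictions a
## PredictionMatrix or a 0/1 matrix. All metrics average per-instance terms.

.as_label_matrix <- function(x) {
  if (is(x, "MultiLabelDataset")) return(x@labelMatrix)
  if (is(x, "PredictionMatrix")) return(x@predicted)
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

.check_shapes <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred)))
    stop("truth and prediction must have identical shape and label order")
  if (!is.null(colnames(truth)) && !is.null(colnames(pred)) &&
      !identical(colnames(truth), colnames(pred)))
    stop("truth and prediction label order differ")
}

#' Hamming loss
#'
#' Mean, over instances, of the size of the symmetric difference between the
#' true label set and the predicted label set divided by the number of
#' labels; equivalently the fraction of mispredicted label cells.
#'
#' @param truth a [MultiLabelDataset-class] or 0/1 matrix.
#' @param pred a [PredictionMatrix-class] or 0/1 matrix of identical shape
#'   and label order.
#' @return proportion in \[0, 1\].
#' @export
hammingLoss <- function(truth, pred) {
  Y <- .as_label_matrix(truth); Z <- .as_label_matrix(pred)
  .check_shapes(Y, Z)
  mean(Y != Z)
}

#' Subset (0/1) accuracy
#'
#' Fraction of instances whose predicted label set equals the true one
#' exactly — the strictest example-based metric.
#'
#' @inheritParams hammingLoss
#' @return proportion in \[0, 1\].
#' @export
subsetAccuracy <- function(truth, pred) {
  Y <- .as_label_matrix(truth); Z <- .as_label_matrix(pred)
  .check_shapes(Y, Z)
  mean(rowSums(Y != Z) == 0L)
}

#' Example-based accuracy (mean per-instance Jaccard index)
#'
#' Mean over instances of |Y_i intersect Z_i| / |Y_i union Z_i|. An instance
#' whose true and predicted sets are both empty contributes 1 (the prediction
#' is exactly right), keeping the metric total and bounded.
#'
#' @inheritParams hammingLoss
#' @return proportion in \[0, 1\].
#' @export
exampleAccuracy <- function(truth, pred) {
  Y <- .as_label_matrix(truth); Z <- .as_label_matrix(pred)
  .check_shapes(Y, Z)
  inter <- rowSums(Y & Z)
  uni <- rowSums(Y | Z)
  term <- ifelse(uni == 0L, 1, inter / pmax(uni, 1L))
  mean(term)
}

#' Example-based precision, recall and F-measure
#'
#' Instance-averaged ratios of the intersection size to a per-instance
#' denominator, combined into an F-measure as the harmonic mean of the two
#' dataset-level averages.
#'
#' Note on denominators: following the defining equations implemented here,
#' the quantity reported as *precision* divides by |Y_i| (the number of truly
#' relevant labels) and *recall* divides by |Z_i| (the number of predicted
#' labels) — the reverse of the most common convention. The F-measure is the
#' harmonic mean and therefore identical under either assignment. Instances
#' with a zero denominator contribute 1 when both sets are empty and 0
#' otherwise; F is defined as 0 when precision + recall = 0.
#'
#' @inheritParams hammingLoss
#' @return named numeric vector `c(precision, recall, fMeasure)`.
#' @export
precisionRecallF <- function(truth, pred) {
  Y <- .as_label_matrix(truth); Z <- .as_label_matrix(pred)
  .check_shapes(Y, Z)
  inter <- rowSums(Y & Z)
  ny <- rowSums(Y == 1L)
  nz <- rowSums(Z == 1L)
  both_empty <- ny == 0L & nz == 0L
  pterm <- ifelse(ny == 0L, ifelse(both_empty, 1, 0), inter / pmax(ny, 1L))
  rterm <- ifelse(nz == 0L, ifelse(both_empty, 1, 0), inter / pmax(nz, 1L))
  precision <- mean(pterm)
  recall <- mean(rterm)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, fMeasure = f)
}

#' All example-based metrics at once
#'
#' @inheritParams hammingLoss
#' @return A [MetricReport-class].
#' @examples
#' Y <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 0), c(0, 0, 0))
#' Z <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
#' multilabelMetrics(Y, Z)
#' @export
multilabelMetrics <- function(truth, pred) {
  prf <- precisionRecallF(truth, pred)
  new("MetricReport",
      hammingLoss = hammingLoss(truth, pred),
      subsetAccuracy = subsetAccuracy(truth, pred),
      accuracy = exampleAccuracy(truth, pred),
      precision = unname(prf["precision"]),
      recall = unname(prf["recall"]),
      fMeasure = unname(prf["fMeasure"]),
      nEvaluated = nrow(.as_label_matrix(truth)))
}

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport over", object@nEvaluated, "instances\n")
  v <- metricVector(object)
  for (nm in names(v)) cat(sprintf("  %-15s %.4f\n", nm, v[[nm]]))
})

#' Flatten a MetricReport to a named numeric vector
#'
#' @param report a [MetricReport-class].
#' @return named numeric vector with the six metrics.
#' @export
metricVector <- function(report) {
  c(hammingLoss = report@hammingLoss,
    subsetAccuracy = report@subsetAccuracy,
    accuracy = report@accuracy,
    precision = report@precision,
    recall = report@recall,
    fMeasure = report@fMeasure)
}
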