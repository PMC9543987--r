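## BR+IG feature selection: information gain per (feature, label) pair on
## the binary-relevance decomposition, aggregated into one ranking.

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for one binary label
#'
#' `IG = H(label) - H(label | feature)` in bits (base-2 logarithm, with
#' `0 * log 0 := 0`). Numeric features are discretized into equal-frequency
#' bins first; missing values form their own category, so no imputation is
#' needed (or wanted) before selection.
#'
#' @param feature numeric or categorical vector.
#' @param label binary 0/1 vector of the same length.
#' @param bins number of equal-frequency bins for numeric features
#'   (default 10).
#' @return information gain in bits (>= 0). A constant label has entropy 0
#'   and therefore IG 0.
#' @export
informationGain <- function(feature, label, bins = 10L) {
  label <- as.integer(label)
  stopifnot(length(feature) == length(label), all(label %in% c(0L, 1L)))
  if (is.numeric(feature)) {
    br <- unique(quantile(feature, probs = seq(0, 1, length.out = bins + 1L),
                          na.rm = TRUE, names = FALSE, type = 7))
    if (length(br) < 2L) {
      cat_f <- rep("bin1", length(feature))
      cat_f[is.na(feature)] <- NA
    } else {
      cat_f <- as.character(cut(feature, breaks = br, include.lowest = TRUE))
    }
  } else {
    cat_f <- as.character(feature)
  }
  cat_f[is.na(cat_f)] <- ".missing"
  n <- length(label)
  hy <- .entropy(table(label) / n)
  if (hy == 0) return(0)
  hcond <- 0
  for (g in split(label, cat_f)) {
    hcond <- hcond + (length(g) / n) * .entropy(table(g) / length(g))
  }
  max(hy - hcond, 0)
}

#' BR+IG feature ranking
#'
#' Decomposes the multilabel dataset into one single-label dataset per
#' condition (binary relevance), computes the information gain of every
#' feature for every label, and aggregates per feature across labels into a
#' single descending ranking. Ties in the aggregate are broken
#' lexicographically by feature name, so the ranking is deterministic and
#' invariant to row order.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param bins equal-frequency bins for numeric features (default 10).
#' @param aggregation `"mean"` (default) or `"max"` over labels.
#' @return A [FeatureRanking-class].
#' @export
brIgRank <- function(dataset, bins = 10L, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  X <- features(dataset)
  Y <- labelMatrix(dataset)
  per <- matrix(0, ncol(X), ncol(Y),
                dimnames = list(colnames(X), colnames(Y)))
  for (j in seq_len(ncol(X)))
    for (l in seq_len(ncol(Y)))
      per[j, l] <- informationGain(X[[j]], Y[, l], bins = bins)
  agg <- if (aggregation == "mean") rowMeans(per) else apply(per, 1L, max)
  ordering <- rownames(per)[order(-agg, rownames(per))]
  new("FeatureRanking", perLabel = per, aggregate = agg,
      ordering = ordering, aggregation = aggregation)
}

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (BR+IG,", object@aggregation,
      "aggregation over", ncol(object@perLabel), "labels)\n")
  top <- head(object@ordering, 10L)
  print(round(object@aggregate[top], 5))
})

#' Select the top-k features of a ranking
#'
#' @param ranking a [FeatureRanking-class].
#' @param k number of features, `1 <= k <= p`. Selections are nested:
#'   the top-5 set is a prefix of the top-10 set.
#' @return character vector of the first `k` feature names.
#' @export
selectTopK <- function(ranking, k) {
  p <- length(ranking@ordering)
  if (k < 1L || k > p) stop("`k` must be between 1 and ", p)
  ranking@ordering[seq_len(k)]
}

#' Serialize a feature ranking to a data.frame (CSV-ready)
#'
#' @param ranking a [FeatureRanking-class].
#' @return data.frame with rank, feature, aggregate score and per-label IGs.
#' @export
rankingTable <- function(ranking) {
  ord <- ranking@ordering
  cbind(data.frame(rank = seq_along(ord), feature = ord,
                   aggregate = unname(ranking@aggregate[ord]),
                   stringsAsFactors = FALSE),
        as.data.frame(ranking@perLabel[ord, , drop = FALSE],
                      row.names = FALSE))
}
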