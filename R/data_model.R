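#' Construct a MultiLabelDataset
#'
#' @param features data.frame of predictor columns (numeric or
#'   character/factor; character columns are converted to factors). May have
#'   zero columns.
#' @param labels matrix or data.frame of binary (0/1) label columns with
#'   unique names; no missing values allowed.
#' @param clone optional logical vector flagging oversampling clones.
#' @return A [MultiLabelDataset-class] object.
#' @examples
#' d <- multiLabelDataset(
#'   data.frame(age = c(40, 55, 62)),
#'   cbind(diabetes = c(0, 1, 1), asthma = c(1, 0, 1))
#' )
#' nInstances(d)
#' @export
multiLabelDataset <- function(features, labels, clone = NULL) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (j in seq_along(features)) {
    if (is.character(features[[j]]) || is.logical(features[[j]]))
      features[[j]] <- factor(features[[j]])
  }
  rownames(features) <- NULL
  rownames(labels) <- NULL
  if (is.null(clone)) clone <- rep(FALSE, nrow(labels))
  new("MultiLabelDataset", features = features, labelMatrix = labels,
      clone = clone)
}

#' @describeIn multiLabelDataset Number of instances (participants).
#' @param x a `MultiLabelDataset`.
#' @export
nInstances <- function(x) nrow(x@labelMatrix)

#' @describeIn multiLabelDataset Ordered label space (condition names).
#' @export
labelSpace <- function(x) colnames(x@labelMatrix)

#' @describeIn multiLabelDataset The n x L integer label matrix.
#' @export
labelMatrix <- function(x) x@labelMatrix

#' @describeIn multiLabelDataset The feature data.frame.
#' @export
features <- function(x) x@features

#' @describeIn multiLabelDataset Logical flags marking oversampling clones.
#' @export
isClone <- function(x) x@clone

setMethod("show", "MultiLabelDataset", function(object) {
  Y <- object@labelMatrix
  cat("MultiLabelDataset:", nrow(Y), "instances,",
      ncol(object@features), "features,", ncol(Y), "labels\n")
  cat("  labels:", paste(colnames(Y), collapse = ", "), "\n")
  prev <- round(100 * colMeans(Y), 1)
  cat("  prevalence (%):", paste(prev, collapse = ", "), "\n")
  if (any(object@clone))
    cat("  oversampling clones:", sum(object@clone), "\n")
})

#' Subset a MultiLabelDataset by row
#'
#' @param x a `MultiLabelDataset`.
#' @param i integer or logical row index.
#' @param j,drop,... ignored (column subsetting is not supported).
#' @export
setMethod("[", "MultiLabelDataset", function(x, i, j, ..., drop = FALSE) {
  multiLabelDataset(x@features[i, , drop = FALSE],
                    x@labelMatrix[i, , drop = FALSE],
                    clone = x@clone[i])
})

#' Load a multilabel dataset from CSV
#'
#' Reads a participant table with a header row, designates the given columns
#' as binary condition labels and the remainder as features. Following the
#' analytic-sample rule, any row with a missing label value is dropped (labels
#' are never imputed) and the number of dropped rows is reported as the
#' `dropped` attribute of the result.
#'
#' Missing feature values may be coded as empty cells or `NA`.
#'
#' @param path path to a CSV file (comma separator, UTF-8).
#' @param labelColumns character vector of label column names; each must be
#'   present and coercible to 0/1.
#' @return A [MultiLabelDataset-class]; `attr(, "dropped")` gives the number
#'   of rows removed for incomplete label information.
#' @export
loadDataset <- function(path, labelColumns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, header = TRUE, na.strings = c("", "NA"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  missing_cols <- setdiff(labelColumns, names(df))
  if (length(missing_cols))
    stop("label column(s) not found: ", paste(missing_cols, collapse = ", "))
  Y <- as.matrix(df[labelColumns])
  if (!is.numeric(Y)) {
    suppressWarnings(storage.mode(Y) <- "numeric")
  }
  bad <- which(!is.na(Y) & !(Y %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary label value at row %d, column '%s'",
                 bad[1, 1], labelColumns[bad[1, 2]]))
  }
  keep <- !apply(is.na(Y), 1L, any)
  dropped <- sum(!keep)
  if (!any(keep)) stop("all rows have incomplete label information")
  X <- df[keep, setdiff(names(df), labelColumns), drop = FALSE]
  out <- multiLabelDataset(X, Y[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Write a multilabel dataset to CSV
#'
#' Inverse of [loadDataset()]: features followed by label columns, `NA` for
#' missing feature cells. A load/write round trip preserves n, the label
#' space, every label value and the feature missingness pattern.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDatasetCsv <- function(dataset, path) {
  df <- cbind(dataset@features, as.data.frame(dataset@labelMatrix))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Fit missing-value fill statistics on a row subset
#'
#' Learns, per feature, the median (numeric) or mode (categorical) over the
#' given rows only — typically a training partition, so that held-out
#' partitions never influence the statistic. A feature entirely missing in
#' the subset falls back to 0 (numeric) or level `"unknown"` (categorical),
#' with a warning.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param rows integer vector of row indices to learn from (default all).
#' @return An [ImputerState-class].
#' @export
fitImputer <- function(dataset, rows = seq_len(nInstances(dataset))) {
  if (length(rows) == 0L) stop("cannot fit an imputer on an empty row subset")
  X <- dataset@features[rows, , drop = FALSE]
  fills <- list()
  types <- character()
  for (nm in names(X)) {
    col <- X[[nm]]
    if (is.numeric(col)) {
      types[nm] <- "numeric"
      v <- col[!is.na(col)]
      if (length(v) == 0L) {
        warning("feature '", nm, "' entirely missing in subset; fill = 0")
        fills[[nm]] <- 0
      } else fills[[nm]] <- median(v)
    } else {
      types[nm] <- "categorical"
      v <- as.character(col[!is.na(col)])
      if (length(v) == 0L) {
        warning("feature '", nm, "' entirely missing in subset; fill = 'unknown'")
        fills[[nm]] <- "unknown"
      } else {
        tab <- table(v)
        fills[[nm]] <- names(tab)[which.max(tab)]  # first mode on ties
      }
    }
  }
  new("ImputerState", fills = fills, types = types)
}

#' Apply fitted fill statistics to a dataset
#'
#' Replaces missing feature cells with the fitted statistic; non-missing
#' cells are left untouched, so the operation is idempotent. Labels are never
#' modified.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param state an [ImputerState-class] fitted with [fitImputer()].
#' @return A [MultiLabelDataset-class] with no missing feature values for the
#'   features covered by `state`.
#' @export
applyImputer <- function(dataset, state) {
  X <- dataset@features
  for (nm in intersect(names(X), names(state@fills))) {
    miss <- is.na(X[[nm]])
    if (!any(miss)) next
    fill <- state@fills[[nm]]
    if (state@types[[nm]] == "categorical") {
      col <- as.character(X[[nm]])
      col[miss] <- as.character(fill)
      X[[nm]] <- factor(col)
    } else {
      X[[nm]][miss] <- fill
    }
  }
  multiLabelDataset(X, dataset@labelMatrix, clone = dataset@clone)
}

#' Encode mixed-type features into a numeric design matrix
#'
#' One-hot encoding expands each categorical feature into indicator columns
#' with the reference (first) level dropped; ordinal encoding maps levels to
#' integer codes. The returned column map supports aggregating per-column
#' importances back to source features by summation.
#'
#' @param dataset a [MultiLabelDataset-class]; for `scheme = "onehot"` no
#'   missing feature values may remain (impute first).
#' @param scheme `"onehot"` or `"ordinal"`.
#' @param levelsMap optional list of per-feature level vectors learned at fit
#'   time; categories unseen in the map encode as all-zero indicators with a
#'   warning.
#' @return list with `matrix` (numeric design matrix), `map` (data.frame
#'   mapping encoded column to source feature) and `levels` (per-feature
#'   level vectors for re-use at prediction time).
#' @export
encodeFeatures <- function(dataset, scheme = c("onehot", "ordinal"),
                           levelsMap = NULL) {
  scheme <- match.arg(scheme)
  X <- dataset@features
  if (scheme == "onehot" && anyNA(X))
    stop("one-hot encoding requires imputed features (no missing values)")
  cols <- list(); map_feature <- character(); map_col <- character()
  levelsOut <- list()
  for (nm in names(X)) {
    col <- X[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- as.numeric(col)
      map_feature <- c(map_feature, nm); map_col <- c(map_col, nm)
    } else {
      lv <- if (!is.null(levelsMap) && !is.null(levelsMap[[nm]]))
        levelsMap[[nm]] else levels(factor(col))
      levelsOut[[nm]] <- lv
      chr <- as.character(col)
      unseen <- !is.na(chr) & !(chr %in% lv)
      if (any(unseen))
        warning("feature '", nm, "': ", sum(unseen),
                " value(s) with unseen category encoded as all-zero")
      if (scheme == "ordinal") {
        code <- match(chr, lv)
        code[unseen] <- 0L
        cols[[nm]] <- as.numeric(code)
        map_feature <- c(map_feature, nm); map_col <- c(map_col, nm)
      } else {
        for (l in lv[-1L]) {       # reference level dropped
          cn <- paste0(nm, "=", l)
          cols[[cn]] <- as.numeric(!is.na(chr) & chr == l)
          map_feature <- c(map_feature, nm); map_col <- c(map_col, cn)
        }
        if (length(lv) == 1L) {    # single-level factor: constant 0 column
          cn <- paste0(nm, "=", lv[1L])
          cols[[cn]] <- rep(0, length(chr))
          map_feature <- c(map_feature, nm); map_col <- c(map_col, cn)
        }
      }
    }
  }
  M <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow = nInstances(dataset), ncol = 0L)
  colnames(M) <- map_col
  list(matrix = M,
       map = data.frame(column = map_col, feature = map_feature,
                        stringsAsFactors = FALSE),
       levels = levelsOut)
}

#' Aggregate encoded-column importances back to source features
#'
#' @param values named numeric vector keyed by encoded column name.
#' @param map the `map` element returned by [encodeFeatures()].
#' @return named numeric vector keyed by source feature (sums of the
#'   importances of its encoded columns).
#' @export
aggregateToFeatures <- function(values, map) {
  feats <- map$feature[match(names(values), map$column)]
  out <- tapply(values, feats, sum)
  setNames(as.numeric(out), names(out))[unique(map$feature)]
}
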