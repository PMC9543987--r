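## Dataset characterization: imbalance measures, multimorbidity descriptives
## and IRLbl-driven random oversampling (ML-ROS).

.label_counts <- function(Y) colSums(Y == 1L)

#' Imbalance profile of a multilabel dataset
#'
#' Computes label cardinality LC (mean labels per instance), label density
#' LD = LC / L, the per-label imbalance ratio IRLbl(y) = max occurrence /
#' occurrence(y), and MeanIR, the average IRLbl over labels.
#'
#' @param dataset a [MultiLabelDataset-class]; every label must occur at
#'   least once.
#' @return An [ImbalanceProfile-class].
#' @examples
#' Y <- cbind(a = rep(1:0, c(6, 4)), b = rep(1:0, c(3, 7)),
#'            c = rep(1:0, c(2, 8)))
#' d <- multiLabelDataset(data.frame(x = 1:10), Y)
#' imbalanceProfile(d)  # IRLbl (1, 2, 3), MeanIR 2
#' @export
imbalanceProfile <- function(dataset) {
  Y <- labelMatrix(dataset)
  cnt <- .label_counts(Y)
  if (any(cnt == 0L))
    stop("label(s) with zero occurrences: ",
         paste(names(cnt)[cnt == 0L], collapse = ", "))
  cardinality <- mean(rowSums(Y))
  irlbl <- max(cnt) / cnt
  new("ImbalanceProfile",
      cardinality = cardinality,
      density = cardinality / ncol(Y),
      irlbl = irlbl,
      meanIR = mean(irlbl))
}

setMethod("show", "ImbalanceProfile", function(object) {
  cat("ImbalanceProfile\n")
  cat(sprintf("  cardinality %.4f  density %.4f  MeanIR %.4f\n",
              object@cardinality, object@density, object@meanIR))
  cat("  IRLbl:\n")
  print(round(object@irlbl, 3))
})

#' Cross-tabulate participants by their number of chronic conditions
#'
#' Buckets instances by the number of positive labels (0, 1, 2, 3, 4, 5+),
#' optionally cross-tabulated against a categorical stratifier (e.g. sex)
#' with within-bucket column percentages.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param stratifier optional name of a categorical feature with no missing
#'   values among counted rows.
#' @return list with `buckets` (named counts over "0".."4", "5+"; sums to n),
#'   `rawCounts` (counts by exact condition number), and when a stratifier is
#'   given, `table` (stratifier levels x buckets counts) and `percent`
#'   (within-column percentages, 1 decimal).
#' @export
conditionCountTable <- function(dataset, stratifier = NULL) {
  Y <- labelMatrix(dataset)
  ncond <- rowSums(Y)
  raw <- table(factor(ncond, levels = 0:max(ncond, 5)))
  bucket <- ifelse(ncond >= 5, "5+", as.character(ncond))
  bucket <- factor(bucket, levels = c("0", "1", "2", "3", "4", "5+"))
  out <- list(buckets = table(bucket), rawCounts = raw)
  if (!is.null(stratifier)) {
    s <- features(dataset)[[stratifier]]
    if (is.null(s)) stop("stratifier feature not found: ", stratifier)
    if (anyNA(s)) stop("stratifier has missing values")
    tab <- table(s, bucket)
    out$table <- tab
    out$percent <- round(100 * sweep(tab, 2L, pmax(colSums(tab), 1L), "/"), 1)
  }
  out
}

#' Multimorbidity prevalence
#'
#' Fraction of instances carrying at least two of the conditions in the
#' label set.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @return proportion in \[0, 1\].
#' @export
multimorbidityPrevalence <- function(dataset) {
  mean(rowSums(labelMatrix(dataset)) >= 2L)
}

#' Condition co-occurrence matrix
#'
#' Entry (y, x) is the prevalence of condition y among participants who have
#' condition x: count(y and x) / count(x). The diagonal is 1. Also returns
#' per-label marginal prevalence and its split into occurrences with at least
#' one co-occurring condition versus isolated occurrences.
#'
#' @param dataset a [MultiLabelDataset-class]; every label must occur.
#' @return list with `conditional` (L x L matrix, rows = y, columns = x),
#'   `prevalence`, `withCooccurrence` and `isolated` (named proportions).
#' @export
cooccurrenceMatrix <- function(dataset) {
  Y <- labelMatrix(dataset)
  cnt <- .label_counts(Y)
  if (any(cnt == 0L))
    stop("label(s) with zero occurrences: ",
         paste(names(cnt)[cnt == 0L], collapse = ", "))
  joint <- crossprod(Y)                       # count(y and x)
  conditional <- sweep(joint, 2L, cnt, "/")
  n <- nrow(Y)
  ncond <- rowSums(Y)
  withco <- colSums(Y == 1L & ncond >= 2L) / n
  list(conditional = conditional,
       prevalence = cnt / n,
       withCooccurrence = withco,
       isolated = cnt / n - withco)
}

#' IRLbl-based multilabel random oversampling (ML-ROS)
#'
#' Iteratively clones instances that carry minority labels: a label is in
#' minority while its IRLbl exceeds the current MeanIR. At each step the
#' rarest qualifying label (in rotation over qualifying labels) receives one
#' clone, drawn uniformly with replacement among current carriers of that
#' label; IRLbl and MeanIR are recomputed after every clone so the stopping
#' rule is exact. A draw whose commit would raise MeanIR (possible when the
#' minority label's carriers also tend to carry the majority label) is
#' rejected and that label excluded from further cloning, making MeanIR
#' non-increasing clone by clone. The loop stops when the clone budget
#' `ceiling(budgetFraction * n)` is exhausted or no cloneable label remains
#' above MeanIR. All original instances are retained; clones are flagged via
#' [isClone()].
#'
#' @param dataset a [MultiLabelDataset-class]; every label must occur.
#' @param budgetFraction clone budget as a fraction of n (default 0.25).
#' @param seed integer seed making the clone draws reproducible.
#' @return A [MultiLabelDataset-class] whose MeanIR is no larger than the
#'   input's. If no label is in minority at entry the input is returned
#'   unchanged with a message.
#' @export
mlrosOversample <- function(dataset, budgetFraction = 0.25, seed = 1L) {
  stopifnot(budgetFraction > 0)
  Y <- labelMatrix(dataset)
  n0 <- nrow(Y)
  cnt <- .label_counts(Y)
  if (any(cnt == 0L))
    stop("label(s) with zero occurrences: ",
         paste(names(cnt)[cnt == 0L], collapse = ", "))
  budget <- ceiling(budgetFraction * n0)
  irlbl <- max(cnt) / cnt
  if (!any(irlbl > mean(irlbl))) {
    message("no minority labels (IRLbl > MeanIR): dataset returned unchanged")
    return(dataset)
  }
  set.seed(seed)
  # carriers per label, kept up to date as clones are appended
  carriers <- lapply(seq_len(ncol(Y)), function(l) which(Y[, l] == 1L))
  cloneSrc <- integer(0)   # source row of each clone, in original row space
  cloneY <- list()
  nrows <- n0
  used <- 0L
  # a label is blocked once a clone for it would raise MeanIR (its carriers
  # also tend to carry the majority label); this keeps MeanIR non-increasing
  blocked <- rep(FALSE, ncol(Y))
  repeat {
    if (used >= budget) break
    meanIR <- mean(irlbl)
    minority <- which(irlbl > meanIR & !blocked)
    if (length(minority) == 0L) break
    # one sweep over current minority labels, rarest first
    minority <- minority[order(-irlbl[minority])]
    progressed <- FALSE
    for (l in minority) {
      if (used >= budget) break
      if (blocked[l] || irlbl[l] <= mean(irlbl)) next
      pick <- carriers[[l]][sample.int(length(carriers[[l]]), 1L)]
      srcY <- if (pick <= n0) Y[pick, ] else cloneY[[pick - n0]]
      pos <- which(srcY == 1L)
      newCnt <- cnt
      newCnt[pos] <- newCnt[pos] + 1L
      newIrlbl <- max(newCnt) / newCnt
      if (mean(newIrlbl) > mean(irlbl) + 1e-12) {  # would worsen: reject
        blocked[l] <- TRUE
        next
      }
      nrows <- nrows + 1L
      cloneY[[length(cloneY) + 1L]] <- srcY
      cloneSrc <- c(cloneSrc, pick)
      for (j in pos) carriers[[j]] <- c(carriers[[j]], nrows)
      cnt <- newCnt
      irlbl <- newIrlbl
      used <- used + 1L
      progressed <- TRUE
    }
    if (!progressed) break
  }
  if (used == 0L) return(dataset)
  Yc <- do.call(rbind, cloneY)
  # resolve clone-of-clone sources back to original rows for the feature copy
  resolve <- function(i) {
    while (i > n0) i <- cloneSrc[i - n0]
    i
  }
  srcRows <- vapply(n0 + seq_len(used), resolve, integer(1))
  Xc <- features(dataset)[srcRows, , drop = FALSE]
  multiLabelDataset(rbind(features(dataset), Xc),
                    rbind(Y, Yc),
                    clone = c(isClone(dataset), rep(TRUE, used)))
}

#' Published cohort descriptives used for arithmetic cross-checks
#'
#' Baseline descriptives of the Brazilian adult-health cohort the synthetic
#' generator emulates, as published: participant counts by number of chronic
#' conditions, the sex split within each group, and group mean ages. These
#' serve as fixed inputs for reconstructing the cohort's headline
#' descriptive statistics (overall multimorbidity prevalence, sex
#' composition, weighted mean age) from the package's own tabulation
#' functions.
#'
#' @return data.frame with columns `conditions` ("0".."4", "5+"), `n`,
#'   `male`, `female`, `meanAge`.
#' @export
publishedDescriptives <- function() {
  data.frame(
    conditions = c("0", "1", "2", "3", "4", "5+"),
    n = c(2238L, 4251L, 4111L, 2550L, 1163L, 523L),
    male = c(1288L, 2194L, 1846L, 960L, 367L, 114L),
    female = c(950L, 2057L, 2265L, 1590L, 796L, 409L),
    meanAge = c(49.3, 51.4, 52.3, 53.2, 54.7, 56.2),
    stringsAsFactors = FALSE
  )
}

#' Rebuild a participant-level micro-dataset from published descriptives
#'
#' Expands the grouped counts of [publishedDescriptives()] into one row per
#' participant: each participant receives a synthetic label set with the
#' correct number of conditions (the "5+" group is represented with exactly
#' five), a sex matching the published cross-tabulation and the group mean
#' age. Only quantities that depend on the number of conditions, sex
#' composition and group means are meaningful on this reconstruction.
#'
#' @param labelCount number of label columns to synthesize (default 10).
#' @return A [MultiLabelDataset-class] with features `sex` and `age`.
#' @export
reconstructPublishedCohort <- function(labelCount = 10L) {
  d <- publishedDescriptives()
  ncond <- c(0:4, 5L)
  rows_n <- integer(0); rows_sex <- character(0); rows_age <- numeric(0)
  for (i in seq_len(nrow(d))) {
    k <- d$n[i]
    rows_n <- c(rows_n, rep(ncond[i], k))
    rows_sex <- c(rows_sex, rep(c("male", "female"), c(d$male[i], d$female[i])))
    rows_age <- c(rows_age, rep(d$meanAge[i], k))
  }
  Y <- matrix(0L, nrow = length(rows_n), ncol = labelCount,
              dimnames = list(NULL, paste0("condition", seq_len(labelCount))))
  for (i in seq_along(rows_n)) if (rows_n[i] > 0L) Y[i, seq_len(rows_n[i])] <- 1L
  multiLabelDataset(data.frame(sex = rows_sex, age = rows_age), Y)
}
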