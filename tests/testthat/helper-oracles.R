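# Brute-force oracles, independent of the package implementation. Each
# works instance by instance / cell by cell with explicit loops and set
# operations, so the vectorized implementations are checked against a
# different computational path.

oracle_metrics <- function(Y, Z) {
  n <- nrow(Y); L <- ncol(Y)
  hl <- 0; sa <- 0; acc <- 0; prec <- 0; rec <- 0
  for (i in seq_len(n)) {
    yi <- which(Y[i, ] == 1); zi <- which(Z[i, ] == 1)
    hl <- hl + (length(setdiff(yi, zi)) + length(setdiff(zi, yi))) / L
    sa <- sa + as.numeric(setequal(yi, zi))
    uni <- union(yi, zi)
    acc <- acc + if (length(uni) == 0) 1 else
      length(intersect(yi, zi)) / length(uni)
    prec <- prec + if (length(yi) == 0) {
      if (length(zi) == 0) 1 else 0
    } else length(intersect(yi, zi)) / length(yi)
    rec <- rec + if (length(zi) == 0) {
      if (length(yi) == 0) 1 else 0
    } else length(intersect(yi, zi)) / length(zi)
  }
  prec <- prec / n; rec <- rec / n
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(hammingLoss = hl / n, subsetAccuracy = sa / n, accuracy = acc / n,
       precision = prec, recall = rec, fMeasure = f)
}

oracle_imbalance <- function(Y) {
  counts <- sapply(seq_len(ncol(Y)), function(l) sum(Y[, l] == 1))
  lc <- sum(Y) / nrow(Y)
  irlbl <- sapply(counts, function(c) max(counts) / c)
  list(cardinality = lc, density = lc / ncol(Y), irlbl = irlbl,
       meanIR = mean(irlbl))
}

# information gain from the explicit joint probability table
oracle_ig <- function(fcat, label) {
  fcat <- as.character(fcat)
  fcat[is.na(fcat)] <- ".missing"
  tab <- table(fcat, label)
  p <- tab / sum(tab)
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hy <- h(colSums(p))
  hjoint <- h(as.numeric(p))
  hf <- h(rowSums(p))
  hy - (hjoint - hf)   # H(Y) - H(Y|F)
}

# composite normalized Gini score by direct per-label arithmetic
oracle_gini_score <- function(Y, leftIdx, w = rep(1 / ncol(Y), ncol(Y))) {
  n <- nrow(Y); nl <- length(leftIdx); nr <- n - nl
  s <- 0
  for (l in seq_len(ncol(Y))) {
    g <- function(rows) {
      p <- mean(Y[rows, l]); 2 * p * (1 - p)
    }
    gp <- g(seq_len(n))
    if (gp <= 0) next
    d <- gp - (nl / n) * g(leftIdx) - (nr / n) * g(setdiff(seq_len(n), leftIdx))
    s <- s + w[l] * d / gp
  }
  s
}

# exhaustive best split over every feature and every left/right partition
# induced by thresholds (numeric) or level subsets (categorical)
oracle_best_split <- function(X, Y, w = rep(1 / ncol(Y), ncol(Y))) {
  best <- list(score = 0)
  for (j in seq_len(ncol(X))) {
    col <- X[[j]]
    if (is.numeric(col)) {
      for (thr in unique(sort(col))[-length(unique(col))]) {
        left <- which(col <= thr)
        s <- oracle_gini_score(Y, left, w)
        if (s > best$score + 1e-12)
          best <- list(score = s, feature = names(X)[j], threshold = thr)
      }
    } else {
      lv <- unique(as.character(col))
      if (length(lv) < 2) next
      for (m in seq_len(2^length(lv) - 2)) {
        sel <- lv[as.logical(bitwAnd(m, 2^(seq_along(lv) - 1)))]
        left <- which(as.character(col) %in% sel)
        if (length(left) == 0 || length(left) == length(col)) next
        s <- oracle_gini_score(Y, left, w)
        if (s > best$score + 1e-12)
          best <- list(score = s, feature = names(X)[j], levels = sel)
      }
    }
  }
  best
}

random_mld <- function(n, L, seed, p = 2) {
  set.seed(seed)
  repeat {
    Y <- matrix(rbinom(n * L, 1L, runif(L, 0.2, 0.7)[rep(seq_len(L),
                                                         each = n)]),
                n, L, dimnames = list(NULL, paste0("y", seq_len(L))))
    if (all(colSums(Y) > 0)) break
  }
  X <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("x", seq_len(p)))))
  multiLabelDataset(X, Y)
}

random_binary <- function(n, L, seed) {
  set.seed(seed)
  matrix(rbinom(n * L, 1L, 0.4), n, L,
         dimnames = list(NULL, paste0("y", seq_len(L))))
}
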