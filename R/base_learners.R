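## Pluggable binary base learners behind a fit/score contract.
## "rf" wraps ranger probability forests (consumes raw mixed-type columns);
## "svm" wraps e1071::svm with Platt-scaled probabilities (requires a numeric
## one-hot design). Both are deterministic given a seed.

#' Specify a binary base learner
#'
#' Defines the learner plugged under the problem-transformation classifiers.
#' The contract is: fit a binary classifier on a design matrix and a 0/1
#' target, and score new instances with a probability in \[0, 1\].
#'
#' @param kind `"rf"` (random forest, via ranger) or `"svm"` (support vector
#'   machine with an RBF kernel, via e1071).
#' @param ... hyperparameters. For `"rf"`: `num.trees` (default 100), `mtry`
#'   (default floor(sqrt(p))), `min.node.size` (default 5). For `"svm"`:
#'   `cost` (default 1), `gamma` (default 1/p).
#' @return list with fields `kind`, `params` and `needsNumeric` (whether the
#'   learner requires a numeric one-hot design matrix).
#' @export
baseLearner <- function(kind = c("rf", "svm"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  list(kind = kind, params = params, needsNumeric = (kind == "svm"))
}

## Fit one binary learner. X: data.frame (rf) or numeric matrix (svm);
## y: 0/1 vector. A constant target yields a constant-rate predictor.
.fit_binary <- function(base, X, y, seed) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    warning("constant training label; using a constant-probability predictor")
    return(list(type = "const", rate = mean(y)))
  }
  p <- ncol(X)
  if (base$kind == "rf") {
    prm <- base$params
    df <- as.data.frame(X)
    df$.y <- factor(y, levels = c(0L, 1L))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = prm$num.trees %||% 100L,
      mtry = prm$mtry %||% max(1L, floor(sqrt(p))),
      min.node.size = prm$min.node.size %||% 5L,
      probability = TRUE, seed = seed, num.threads = 1L,
      respect.unordered.factors = "order")
    list(type = "ranger", model = fit, columns = colnames(X))
  } else {
    prm <- base$params
    set.seed(seed)
    fit <- e1071::svm(
      x = as.matrix(X), y = factor(y, levels = c(0L, 1L)),
      kernel = "radial",
      cost = prm$cost %||% 1,
      gamma = prm$gamma %||% (1 / max(p, 1L)),
      probability = TRUE, scale = TRUE)
    list(type = "svm", model = fit, columns = colnames(X))
  }
}

## Score new instances with a fitted binary learner -> probability vector.
.score_binary <- function(fit, X) {
  if (fit$type == "const") return(rep(fit$rate, nrow(X)))
  if (fit$type == "ranger") {
    pr <- predict(fit$model, data = as.data.frame(X),
                  num.threads = 1L)$predictions
    as.numeric(pr[, "1"])
  } else {
    pr <- predict(fit$model, newdata = as.matrix(X), probability = TRUE)
    pm <- attr(pr, "probabilities")
    as.numeric(pm[, "1"])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
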