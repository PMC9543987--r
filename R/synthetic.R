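## Latent-factor logistic generator of synthetic cohorts emulating a large
## Brazilian adult-health cohort: 31 mixed-type predictors with realistic
## dependence, 10 chronic-condition labels drawn from per-label logistic
## models sharing two latent factors (a cardio-metabolic and a
## musculoskeletal-mental factor), which induce the label co-occurrence
## patterns the multilabel classifiers are meant to exploit.

## Label order groups each co-occurrence pattern contiguously
## (cardio-metabolic block first, then the musculoskeletal-mental block),
## which is also the default classifier-chain order.
.COND <- c("dyslipidemia", "diabetes", "heart_disease", "kidney_disease",
           "cirrhosis", "cancer", "migraine", "common_mental_disorder",
           "joint_problems", "asthma")

## Default per-label target prevalences. The three largest are the cohort's
## published values; the remaining seven are plausible values chosen so that
## the label cardinality (sum of prevalences) is 1.86 and MeanIR
## (mean of max(p)/p) is approximately 3.82, with every prevalence >= 5%
## (the cohort's inclusion rule for conditions).
.TARGETS <- c(dyslipidemia = 0.442, diabetes = 0.220, heart_disease = 0.060,
              kidney_disease = 0.093, cirrhosis = 0.058, cancer = 0.065,
              migraine = 0.295, common_mental_disorder = 0.267,
              joint_problems = 0.237, asthma = 0.123)

## Latent-factor loadings (cardio-metabolic, mental). The cardio factor
## loads on the dyslipidemia/diabetes/heart-disease analogs, the mental
## factor on the common-mental-disorder/migraine/joint analogs. Magnitudes
## are set so the simulated conditional co-occurrences match the published
## pattern strengths (dyslipidemia ~63% among diabetics / ~66% among heart
## disease; migraine ~51% among common mental disorder).
.LOADINGS <- matrix(
  c(0.80, 0.0,   # dyslipidemia
    0.80, 0.0,   # diabetes
    0.80, 0.0,   # heart_disease
    0.35, 0.0,   # kidney_disease
    0.20, 0.0,   # cirrhosis
    0.20, 0.0,   # cancer
    0.0, 1.60,   # migraine
    0.0, 1.60,   # common_mental_disorder
    0.0, 1.60,   # joint_problems
    0.0, 0.60),  # asthma
  ncol = 2L, byrow = TRUE,
  dimnames = list(.COND, c("cardio", "mental")))

## Per-label coefficients on derived (standardized) covariates. The BMI
## analog carries the largest aggregate signal by design, followed by
## systolic BP, age and sex, mirroring the predictor ordering the analysis
## is expected to recover.
.COEFS <- list(
  dyslipidemia = c(zbmi = 0.65, zsbp = 0.35, zage = 0.20, zwhr = 0.25,
                   zdbp = 0.15),
  migraine = c(female = 0.65, sleeping_problem = 0.25, zage = -0.20),
  common_mental_disorder = c(female = 0.45, sleep_symptom = 0.40,
                             sleeping_problem = 0.35, zage = -0.10),
  joint_problems = c(zage = 0.25, zbmi = 0.35, female = 0.25,
                     sleep_symptom = 0.20),
  diabetes = c(zbmi = 0.70, zage = 0.25, zsbp = 0.25, zwhr = 0.25,
               fh_diabetes = 0.35),
  asthma = c(fh_asthma = 0.45, female = 0.15),
  kidney_disease = c(zage = 0.15, zsbp = 0.20, zbmi = 0.15),
  cancer = c(zage = 0.30, fh_cancer = 0.30, smoking_current = 0.15),
  heart_disease = c(zage = 0.30, zsbp = 0.30, zbmi = 0.25, zdbp = 0.15,
                    fh_heart_disease = 0.30),
  cirrhosis = c(alcohol_excessive = 0.45, zage = 0.10)
)

#' Build a synthetic-cohort configuration
#'
#' @param n cohort size (default 14836, the analytic sample size of the
#'   emulated cohort).
#' @param targets named per-label target prevalences in (0, 1).
#' @param intercepts named per-label logistic intercepts; `NA` values are
#'   filled by [calibrateIntercepts()].
#' @param loadings labels x 2 matrix of latent-factor loadings
#'   (cardio-metabolic, mental).
#' @param coefs named list of per-label coefficient vectors over derived
#'   covariates.
#' @param missingRate completely-at-random feature missingness (default
#'   0.02; labels are never masked).
#' @param seed integer seed.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(n = 14836L, targets = .TARGETS,
                            intercepts = NULL, loadings = .LOADINGS,
                            coefs = .COEFS, missingRate = 0.02, seed = 1L) {
  if (any(targets <= 0) || any(targets >= 1))
    stop("target prevalences must lie strictly in (0, 1)")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (n < 1L) stop("n must be positive")
  if (is.null(intercepts))
    intercepts <- setNames(rep(NA_real_, length(targets)), names(targets))
  if (!all(is.finite(unlist(coefs))))
    stop("coefficients must be finite")
  new("SyntheticConfig", n = as.integer(n), targets = targets,
      intercepts = intercepts, loadings = loadings, coefs = coefs,
      missingRate = missingRate, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: n =", object@n, ", seed =", object@seed,
      ", missingness =", object@missingRate, "\n")
  cat("  target prevalences:\n")
  print(round(object@targets, 3))
})

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

.rcat <- function(n, levels, probs) {
  factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
}

## Draw the 31 predictors plus the two latent factors; returns the raw
## feature data.frame and the derived covariate matrix the label models use.
.synth_covariates <- function(n) {
  age <- .rtruncnorm(n, 52.1, 9.1, 35, 75)
  sex <- .rcat(n, c("male", "female"), c(0.456, 0.544))
  female <- as.numeric(sex == "female")
  male <- 1 - female
  education <- .rcat(n, c("never_to_elementary", "secondary",
                          "undergraduate", "postgraduate"),
                     c(0.127, 0.348, 0.400, 0.125))
  race <- .rcat(n, c("white", "pardo", "black", "indigenous", "asian"),
                c(0.521, 0.282, 0.161, 0.010, 0.026))
  marital_status <- .rcat(n, c("single", "not_single"), c(0.339, 0.661))
  income <- rlnorm(n, meanlog = log(938.2) - 0.245, sdlog = 0.7)
  children <- .rcat(n, c("no", "yes"), c(0.25, 0.75))
  maternal_education <- .rcat(n, c("never_attended", "incomplete_elementary",
                                   "elementary", "secondary",
                                   "undergraduate"),
                              c(0.15, 0.30, 0.25, 0.20, 0.10))
  smoking <- .rcat(n, c("never", "past", "current"), c(0.57, 0.30, 0.13))
  alcohol <- .rcat(n, c("none", "moderate", "excessive"),
                   c(0.30, 0.60, 0.10))
  physical_activity <- .rcat(n, c("weak", "moderate", "strong"),
                             c(0.60, 0.25, 0.15))
  activity_days <- sample(0:7, n, replace = TRUE,
                          prob = c(0.35, 0.10, 0.15, 0.13, 0.09, 0.07,
                                   0.05, 0.06))
  sleep_symptom <- rbinom(n, 1L, 0.35)
  sleeping_problem <- rbinom(n, 1L, 0.30)
  fruit_consumption <- .rcat(n, c("high", "daily", "weekly", "rarely"),
                             c(0.25, 0.40, 0.25, 0.10))
  vegetable_consumption <- .rcat(n, c("high", "daily", "weekly", "rarely"),
                                 c(0.30, 0.40, 0.20, 0.10))
  coffee <- .rcat(n, c("no", "caffeinated", "decaffeinated"),
                  c(0.12, 0.83, 0.05))
  bmi <- rnorm(n, 26.9 + 0.04 * (age - 52.1), 4.6)
  systolic_bp <- rnorm(n, 119 + 0.45 * (age - 52.1) + 0.5 * (bmi - 26.9) +
                         4 * male, 14)
  diastolic_bp <- rnorm(n, 76 + 0.15 * (age - 52.1) + 0.45 * (bmi - 26.9) +
                          2.5 * male, 9)
  heart_rate <- rnorm(n, 72, 9)
  waist_hip_ratio <- rnorm(n, 0.87 + 0.065 * male + 0.0015 * (age - 52.1) +
                             0.004 * (bmi - 26.9), 0.05)
  fh <- data.frame(
    fh_hypertension = rbinom(n, 1L, 0.55),
    fh_diabetes = rbinom(n, 1L, 0.33),
    fh_heart_disease = rbinom(n, 1L, 0.30),
    fh_stroke = rbinom(n, 1L, 0.18),
    fh_cerebrovascular = rbinom(n, 1L, 0.10),
    fh_angioplasty = rbinom(n, 1L, 0.08),
    fh_sudden_death = rbinom(n, 1L, 0.07),
    fh_asthma = rbinom(n, 1L, 0.12),
    fh_cancer = rbinom(n, 1L, 0.28))
  X <- cbind(
    data.frame(age = age, sex = sex, education = education, race = race,
               marital_status = marital_status, income = income,
               children = children, maternal_education = maternal_education,
               smoking = smoking, alcohol = alcohol,
               physical_activity = physical_activity,
               activity_days = activity_days,
               sleep_symptom = sleep_symptom,
               sleeping_problem = sleeping_problem,
               fruit_consumption = fruit_consumption,
               vegetable_consumption = vegetable_consumption,
               coffee = coffee, bmi = bmi, systolic_bp = systolic_bp,
               diastolic_bp = diastolic_bp, heart_rate = heart_rate,
               waist_hip_ratio = waist_hip_ratio),
    fh)
  z <- function(v) (v - mean(v)) / sd(v)
  derived <- cbind(
    zage = z(age), zbmi = z(bmi), zsbp = z(systolic_bp),
    zdbp = z(diastolic_bp), zwhr = z(waist_hip_ratio),
    female = female, sleep_symptom = sleep_symptom,
    sleeping_problem = sleeping_problem,
    alcohol_excessive = as.numeric(alcohol == "excessive"),
    smoking_current = as.numeric(smoking == "current"),
    fh_diabetes = fh$fh_diabetes, fh_asthma = fh$fh_asthma,
    fh_cancer = fh$fh_cancer, fh_heart_disease = fh$fh_heart_disease)
  factors <- cbind(cardio = rnorm(n), mental = rnorm(n))
  list(X = X, derived = derived, factors = factors)
}

.synth_linpred <- function(config, derived, factors) {
  lbl <- names(config@targets)
  eta <- matrix(0, nrow(derived), length(lbl),
                dimnames = list(NULL, lbl))
  for (l in lbl) {
    cf <- config@coefs[[l]]
    if (length(cf))
      eta[, l] <- derived[, names(cf), drop = FALSE] %*% cf
    eta[, l] <- eta[, l] +
      factors %*% config@loadings[l, c("cardio", "mental")]
  }
  eta
}

#' Generate a synthetic cohort
#'
#' Draws the 31 predictors from per-type distributions with realistic
#' dependence (age drifts blood pressure and BMI, sex shifts the waist-hip
#' ratio and blood pressure), draws two standard-normal latent factors per
#' participant, then draws each condition
#' `Bernoulli(plogis(alpha_l + beta_l . x_i + lambda_l . f_i))`. Feature
#' values are finally masked completely at random at the configured rate;
#' labels are never masked. Fully reproducible given the config seed.
#'
#' @param config a [SyntheticConfig-class] with calibrated (non-`NA`)
#'   intercepts; see [defaultSyntheticConfig()] and [calibrateIntercepts()].
#' @return A [MultiLabelDataset-class] with n rows, 31 features and 10
#'   condition labels. Warns if a label comes out degenerate (prevalence
#'   below 0.1% or above 99.9%).
#' @export
generateCohort <- function(config) {
  if (anyNA(config@intercepts))
    stop("config has uncalibrated intercepts; run calibrateIntercepts()")
  set.seed(config@seed)
  n <- config@n
  cov <- .synth_covariates(n)
  eta <- .synth_linpred(config, cov$derived, cov$factors)
  lbl <- names(config@targets)
  Y <- matrix(0L, n, length(lbl), dimnames = list(NULL, lbl))
  for (l in lbl)
    Y[, l] <- rbinom(n, 1L, plogis(config@intercepts[[l]] + eta[, l]))
  prev <- colMeans(Y)
  if (any(prev < 0.001 | prev > 0.999))
    warning("degenerate label(s): ",
            paste(lbl[prev < 0.001 | prev > 0.999], collapse = ", "))
  X <- cov$X
  if (config@missingRate > 0) {
    for (j in seq_along(X)) {
      mask <- runif(n) < config@missingRate
      X[[j]][mask] <- NA
    }
  }
  multiLabelDataset(X, Y)
}

#' Calibrate the generator's intercepts to target prevalences
#'
#' For each label, solves for the logistic intercept that makes the
#' simulated marginal prevalence match the target, by monotone root-finding
#' on a fixed large simulated covariate sample (fixed seed, so the
#' calibration is deterministic). Raising a target strictly raises the
#' returned intercept.
#'
#' @param config a [SyntheticConfig-class].
#' @param targets named target prevalences (default `config@targets`).
#' @param tolerance maximum allowed |empirical - target| on the calibration
#'   sample (default 0.005).
#' @param nSim calibration sample size (default 40000).
#' @param seed seed of the calibration sample.
#' @return The config with calibrated intercepts (and `targets` updated).
#' @export
calibrateIntercepts <- function(config, targets = config@targets,
                                tolerance = 0.005, nSim = 40000L,
                                seed = 99L) {
  if (any(targets <= 0) || any(targets >= 1))
    stop("targets must lie strictly in (0, 1)")
  set.seed(seed)
  cov <- .synth_covariates(nSim)
  eta <- .synth_linpred(config, cov$derived, cov$factors)
  alphas <- config@intercepts
  for (l in names(targets)) {
    f <- function(a) mean(plogis(a + eta[, l])) - targets[[l]]
    root <- uniroot(f, c(-15, 15), tol = 1e-8)
    alphas[[l]] <- root$root
    if (abs(f(root$root)) > tolerance)
      stop("calibration failed for label '", l, "': residual ",
           signif(abs(f(root$root)), 3))
  }
  config@intercepts <- alphas
  config@targets[names(targets)] <- targets
  config
}

## Frozen intercepts of the default configuration, produced once by
## calibrateIntercepts() on the default coefficient/loading structure
## (nSim = 40000, seed = 99). Regenerate with calibrateIntercepts() after
## any change to .COEFS / .LOADINGS.
.DEFAULT_INTERCEPTS <- c(
  dyslipidemia = -0.310907, diabetes = -1.759045, heart_disease = -3.279237,
  kidney_disease = -2.373197, cirrhosis = -2.862474, cancer = -2.836204,
  migraine = -1.703174, common_mental_disorder = -1.956994,
  joint_problems = -1.911297, asthma = -2.239540)

#' Default calibrated synthetic-cohort configuration
#'
#' The configuration whose simulated cohort matches the emulated cohort's
#' published marginal statistics: maximum condition prevalence 44.2%
#' (dyslipidemia analog), label cardinality approximately 1.86 and MeanIR
#' approximately 3.82 at n = 14836.
#'
#' @param n cohort size (default 14836).
#' @param seed integer seed.
#' @param loadingScale multiplier on the latent-factor loadings; 0 gives
#'   conditionally independent labels (the no-dependence null). Values
#'   other than 1 re-calibrate the intercepts on the fly.
#' @return A calibrated [SyntheticConfig-class].
#' @export
defaultSyntheticConfig <- function(n = 14836L, seed = 1L,
                                   loadingScale = 1) {
  cfg <- syntheticConfig(n = n, seed = seed)
  if (loadingScale == 1) {
    cfg@intercepts <- .DEFAULT_INTERCEPTS
    cfg
  } else {
    cfg@loadings <- cfg@loadings * loadingScale
    calibrateIntercepts(cfg)
  }
}
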