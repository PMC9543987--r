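---
title: "Predicting multimorbidity with multilabel classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multimorbidity with multilabel classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MultiMorbML)
```

## The problem

Multimorbidity — carrying two or more chronic conditions at once — is most
naturally modelled as a *multilabel* prediction problem: for each
participant we predict a subset of a fixed set of conditions, not a single
class and not a disease count. MultiMorbML implements the full pipeline for
this task on a cohort of adults with mixed sociodemographic, lifestyle,
anthropometric and family-history predictors and ten binary chronic
conditions: example-based evaluation metrics, imbalance characterization
and oversampling, three problem-transformation classifiers plus one
algorithm-adaptation classifier, information-gain feature selection, and a
leakage-safe repeated stratified cross-validation harness. Because the
cohort that motivated this design is not publicly deposited, the package
ships a synthetic-cohort generator with the same statistical structure, so
every stage is testable end to end without any data download.

## Data model

A `MultiLabelDataset` couples a mixed-type feature table (numeric or
categorical, missing values allowed) with an `n x L` binary label matrix
(no missing values: rows with incomplete condition information are dropped
at load time — the analytic-sample rule — and never imputed). Labels are
deliberately second-class citizens of imputation: fill statistics
(median/mode) are learned from feature columns of a designated row subset
only, so the cross-validation harness can fit them on training partitions.

Two imputation modes exist because the defensible readings of fold-internal
imputation differ: `"train"` (default) fits on the training partition and
applies the same statistics to both partitions; `"separate"` fits on each
partition independently. The default is the stricter, more common practice;
the alternative is one literal reading of partition-wise imputation and is
kept behind a flag.

## Evaluation metrics

All metrics are example-based (averaged per instance). For truth sets
$Y_i$ and predictions $Z_i$ over $L$ labels:

- Hamming loss $= \frac{1}{n}\sum_i |Y_i \,\Delta\, Z_i| / L$;
- subset accuracy $= \frac{1}{n}\sum_i [\![Y_i = Z_i]\!]$;
- accuracy $= \frac{1}{n}\sum_i |Y_i \cap Z_i| / |Y_i \cup Z_i|$;
- an F-measure as the harmonic mean of two instance-averaged ratios, one
  dividing $|Y_i \cap Z_i|$ by $|Y_i|$ and one by $|Z_i|$.

Two conventions needed fixing where the defining formulas are silent.
First, zero denominators: an instance whose true and predicted sets are
both empty contributes 1 (the prediction is exactly right); if only one
set is empty it contributes 0. This keeps every metric total and bounded in
$[0,1]$. Second, the quantity named *precision* here divides by $|Y_i|$
and *recall* by $|Z_i|$ — the reverse of the usual convention, kept
deliberately to match the defining equations as printed; the F-measure is
symmetric in its two arguments, so it is unaffected. F is computed from the
two dataset-level averages (not per-instance F), and is defined 0 when
both averages are 0.

## Imbalance and oversampling

Label cardinality LC (mean conditions per participant), density LC/L, and
the per-label imbalance ratio IRLbl(y) = (count of the most frequent
label)/(count of y) characterize the dataset; MeanIR averages IRLbl over
labels. ML-ROS oversampling clones instances carrying *minority* labels
(IRLbl above the current MeanIR), drawing uniformly with replacement among
current carriers. IRLbl and MeanIR are recomputed after **every** clone, so
the stopping rule (no label above MeanIR, or the clone budget exhausted) is
exact and cannot overshoot on small data. The budget defaults to 25% of n
— the usual default in the resampling literature, since the original
percentage is unreported — and is configurable. Clones are flagged, all
original rows are retained, and MeanIR never increases.

## Classifiers

Three problem-transformation methods run over a pluggable binary
base-learner contract (`fit` on a design matrix and 0/1 target, `score`
to a probability), with random-forest (ranger) and RBF-SVM (e1071) base
learners provided:

- **BR** (binary relevance): one independent learner per label.
- **CC** (classifier chain): learners in a fixed order; the k-th sees the
  *true* values of the preceding labels at training time and the
  *thresholded predictions* of its predecessors at inference — the
  standard sequential-prediction reading, since feeding true labels is
  impossible at test time.
- **DBR** (dependent binary relevance): each label's learner sees the true
  values of all *other* labels at training; at inference an internal BR
  stage estimates the other labels first (the standard two-stage DBR).

The chain order defaults to the dataset's label-column order and is
configurable (or seeded-random); CC results genuinely depend on it, which
is why the synthetic generator orders its label space by co-occurrence
pattern so the default chain traverses each pattern contiguously.
Probabilities are thresholded at 0.5 with ties predicting positive. A label
constant in training degrades to a constant-rate predictor with a warning
rather than failing an entire fold. Label-valued features are passed as
numeric 0/1 columns.

## The multivariate random forest

The algorithm-adaptation method grows trees on all labels jointly. A
candidate split of a node is scored by the composite normalized Gini index

$$S = \sum_l w_l \, \frac{\Delta \mathrm{Gini}_l}{\mathrm{Gini}_l(\mathrm{parent})},
\qquad \mathrm{Gini}_l = 2 p_l (1 - p_l),$$

with labels pure at the parent contributing 0. The label weights $w_l$
implement the weighted covariance structure: uniform weights (identity
structure) are the default; a compound-symmetry-style option weights each
label by its mean absolute correlation with the other labels. An
autoregressive structure is deliberately not offered — it presumes an
ordering of the outcomes, which unordered disease labels do not have.
The reference description of this splitting rule names the structures
without printing formulas; the normalized weighted sum implemented here is
the minimal faithful reading, and the normalization makes per-label
impurity decreases comparable across labels of different prevalence.

Numeric splits are placed at midpoints between sorted distinct values.
Categorical splits scan prefix partitions of the levels ordered by
weighted positive rate (the classical ordering trick), giving genuine
level-subset splits without one-hot encoding. Ties between candidate
splits go to the first candidate in sampled order, making fits bit-identical
under a fixed seed. Defaults are the standard forest choices: 500 trees,
`mtry = ceiling(sqrt(p))`, minimum node size 5. The split search,
prediction and permutation importance are implemented in C++ (as the
field's forest packages do), with all randomness drawn from R's RNG.

Permutation importance follows the generalized permutation scheme: a
feature's values are shuffled among each tree's out-of-bag rows, out-of-bag
predictions are recomputed, and the importance is the mean increase in
Hamming loss over (by default) 100 runs. Hamming loss is the chosen loss
because it is the pipeline's headline metric; the loss actually used by
the original analysis is unreported.

## Feature selection

BR+IG decomposes the multilabel data into one single-label problem per
condition and computes the information gain of each feature for each label
(base-2 entropy; numeric features discretized into 10 equal-frequency bins;
missing values form their own bin, so selection needs no imputation and
cannot leak fill statistics). Per-feature scores aggregate across labels by
unweighted mean (max is available); ties break lexicographically, so the
ranking is deterministic and row-order invariant. The discretization and
aggregation rule of the original analysis are unreported; both are exposed
in the configuration.

## Cross-validation harness

`runCvExperiment()` implements repeated (default 5x) stratified 10-fold
cross-validation with nested 3-fold tuning. Fold assignment uses iterative
stratification: labels are processed rarest first, and each instance
carrying the current label goes to the fold with the greatest remaining
demand for that label. Inside each fold, in order: per-fold feature
selection (optional), imputation, ML-ROS of the training partition only
(optional), inner-CV tuning by Hamming loss, final fit, evaluation on the
untouched test partition. Every fold records which rows each stage
touched; the test suite asserts the intersection with test rows is empty,
so leakage-freedom is checked, not assumed.

Tuning grids are small and standard (forests:
`mtry in {ceiling(sqrt(p)), ceiling(p/3)}`, min node size in {5, 20};
SVM: cost in {0.1, 1, 10}, gamma in {1/p, 4/p}); the original grids are
unreported. Feature curves rank features per training partition by default
(leakage-safe); a global-ranking mode reproduces the simpler
one-ranking-for-all workflow for comparability, at the price of selection
leakage. The master seed spawns per-repeat and per-fold child seeds
deterministically, so a report is reproducible end to end.

## The synthetic cohort generator

The generator emulates the structure of the motivating cohort of 14836
Brazilian adults: 31 predictors (age, sex, education, race, marital
status, income, children, maternal education; smoking, alcohol, physical
activity and days, sleep flags, fruit/vegetable/coffee consumption; BMI,
systolic and diastolic blood pressure, heart rate, waist-hip ratio; nine
family-history flags) with realistic dependence — age drifts blood
pressure and BMI, sex shifts the waist-hip ratio — and ten conditions
drawn from per-label logistic models:

$$Y_{il} \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}
 (\alpha_l + \beta_l^\top x_i + \lambda_{l,c} f_{c,i} + \lambda_{l,m} f_{m,i})\right),$$

where $f_c, f_m \sim N(0,1)$ are shared cardio-metabolic and
musculoskeletal-mental latent factors. A latent-factor construction was
chosen over copulas because effect sizes stay interpretable, marginal
prevalences calibrate by one-dimensional root-finding, and the two named
co-occurrence patterns fall out directly.

Calibration targets: the three largest prevalences are the published
values (dyslipidemia 44.2%, migraine 29.5%, common mental disorder 26.7%);
the remaining seven conditions' prevalences are not printed as numbers
anywhere, so they were chosen once as plausible values constrained to
reproduce the published label cardinality (1.86 = the sum of prevalences)
and MeanIR (3.82), with every prevalence at or above the 5% inclusion
threshold: joint problems 0.237, diabetes 0.220, asthma 0.123, kidney
disease 0.093, cancer 0.065, heart disease 0.060, cirrhosis 0.058.
Intercepts $\alpha_l$ are calibrated by monotone root-finding on a fixed
simulated covariate sample of 40000 (deterministic given its seed); the
defaults ship pre-calibrated.

Loading magnitudes were set so the simulated conditional co-occurrences
match the published pattern strengths — dyslipidemia reaches ~63% among
diabetics and ~66% among heart-disease carriers, migraine ~51% among
common-mental-disorder carriers — giving cardio loadings of 0.8 on the
dyslipidemia/diabetes/heart-disease analogs (0.35 kidney, 0.2
cancer/cirrhosis) and mental loadings of 1.6 on the
migraine/common-mental-disorder/joint analogs (0.6 asthma). Coefficients
are set so the BMI analog carries the largest aggregate signal, followed
by systolic blood pressure, age and sex — the predictor ordering the
pipeline is expected to recover — and are overridable. Feature values are
masked completely at random at 2% (labels never), matching the small
missing fractions of the emulated cohort.

What the generator does **not** reproduce: the real cohort's joint feature
distribution, its income distribution and study-center effects, outcome
misclassification from self-report, and any missingness mechanism beyond
MCAR. Passing tests therefore demonstrate that the pipeline recovers
structure *of the kind the cohort is believed to have*, not performance on
the real data; published performance values from the non-public cohort are
structural references only, never numeric targets here.

## Problem sizes used by the test suite

The heavier properties are checked at deliberately desk-scale sizes chosen
as the smallest that give stable verdicts: dependence recovery (CC and DBR
versus BR in subset accuracy) on cohorts of 2000 with a 1400/600 split over
20 fixed seeds, with a 10-seed zero-loading null arm; structure recovery
(the BMI analog ranking first in both BR+IG and permutation importance) on
cohorts of 1500 over 20 fixed seeds with 150-tree forests and 25
permutation runs; metric and imbalance oracles on 1000 and 100 random
instances respectively. The forest-versus-base-learner settings in those
suites (60-80 trees, mtry 20) trade a little variance for runtime; the
package defaults remain the standard ones.

## Known limitations

- CC feeds thresholded (not probabilistic) predecessor predictions, the
  standard reading; ensembles of chains and probability calibration are
  out of scope.
- The multivariate forest has no surrogate splits: features must be
  imputed before fitting (trees with native missing-value handling are a
  possible extension).
- No label-powerset or ranking-based methods, no per-label (macro/micro)
  metrics, no significance testing between methods.
- Serialized models are R objects; cross-version stability of the
  artifacts is not guaranteed.
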