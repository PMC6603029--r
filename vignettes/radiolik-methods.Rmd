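---
title: "radiolik: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radiolik: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiolik)
```

# The problem

Radiomic features are quantitative descriptors — shape statistics and
gray-level texture statistics — computed from a segmented tumor region in a
CT image. `radiolik` implements a complete workflow for turning a table of
such features (one row per nodule, one column per feature) into a
two-feature diagnostic *signature* and a closed-form *likelihood function*
whose value near 1 indicates malignancy and near 0 benignity. The package
consumes precomputed feature tables only; image acquisition, segmentation
and feature extraction are upstream of its scope.

The workflow has five stages:

1. **Reliability/discriminability screen** — drop features that are not
   stable across same-day repeat scans or that do not separate the classes.
2. **Consensus ranking** — score the surviving features with a bank of
   ranking algorithms and average the scores with equal weights.
3. **Signature selection** — pick the best shape feature and the best
   texture feature from the top of the consensus list.
4. **Likelihood modeling** — evaluate, or refit, one of two published
   nonlinear functional forms on the signature pair.
5. **Evaluation** — threshold at y ≥ 0.51 and report confusion-matrix
   metrics and ROC/AUC.

# Data model

`RadiomicsExperiment` extends `SummarizedExperiment`: features are rows,
samples are columns, the assay holds the numeric values, `rowData()` the
feature class and kind, `colData()` the optional 0/1 malignancy label.
Feature class is encoded PyRadiomics-style in the column-name prefix
(`shape_Volume`, `glcm_SumEntropy`, ...) over seven classes — shape,
first-order, GLCM, GLDM, GLSZM, GLRLM, NGTDM — and *kind* is shape for the
shape class, texture for the other six. Unknown prefixes default to
first-order with a warning rather than an error, so foreign tables load.
CSV is the single exchange format; values are serialized with
repr-faithful decimals so a write/read round trip is bit-identical.

# Reliability and discriminability screen

Two conjunctive gates, applied in one pass (their order is irrelevant):

* **Test–retest reliability.** Lin's concordance correlation coefficient
  between paired measurements,
  CCC = 2·cov(x,y) / (var(x) + var(y) + (mean(x) − mean(y))²),
  must exceed 0.85 (strict). We default to population (1/n) moments — the
  original estimator — with a `moments = "sample"` switch, since either
  convention is defensible and they differ only by O(1/n).
* **Discriminability.** The Kruskal–Wallis rank test of the feature against
  the binary label (mid-rank ties, tie correction, chi-square reference
  with k − 1 degrees of freedom, via `stats::kruskal.test`) must reject at
  α = 0.05 (strict). No multiplicity correction is applied: the screen is
  deliberately permissive, and the downstream ranking stage, not the
  screen, is responsible for final feature choice.

A constant feature makes the Kruskal–Wallis statistic degenerate; we return
p = 1 with a warning instead of erroring so that batch screening never
aborts, which also guarantees constant features are dropped (p = 1 ≥ α).
A feature whose CCC is undefined (both columns constant with equal means)
fails the reliability gate only if that gate was requested.

# The ranker bank

Practically every published radiomics pipeline ranks features with one
algorithm chosen ad hoc; averaging a *bank* of rankers with equal weights
makes the ordering much less sensitive to that choice. We implement a
representative, fully specified member set per group behind a uniform
interface (`RankerOutput`: raw scores plus orientation), because several
algorithms in the wider literature (ILFS, neighborhood component analysis,
concave optimization, local-learning clustering, MCFS, greedy
reconstruction) are not specified tightly enough for bit-exact
reproduction. Additional rankers can be passed to `rankFeatures()` without
touching the consensus logic.

**Supervised (wrapper) group** — uses labels:

* *Fisher score*: Σ_c n_c(μ_c − μ)² / Σ_c n_c σ²_c with population class
  variances; zero within-class variance maps to the maximal finite
  score + 1 with a warning.
* *ReliefF*: features min-max scaled to [0, 1], Manhattan neighbor search,
  every sample an anchor (deterministic, no subsampling), k = 10 hits and
  misses (truncated for small classes); weights in [−1, 1].
* *Mutual information*: 10 equal-width bins per feature, MI with the label
  in nats.

**Unsupervised (filter) group** — labels ignored:

* *Laplacian score* and *SPEC*: both operate on the same kNN heat-kernel
  graph (Euclidean distances, k = 5, union-symmetrized, weights
  exp(−d²/σ²) with σ = the mean kNN distance). The Laplacian score is the
  Rayleigh quotient of the degree-centered feature on L = D − W (lower =
  smoother = better); SPEC scores the degree-normalized unit feature on
  the normalized Laplacian. Because raw radiomic scales can make d ≫ σ,
  the edge-weight exponent is floored at −700 so retained edges never
  underflow to zero degree.
* *Minimum redundancy*: −mean |Pearson r| against all other features.
* *Min-max variance*: population variance after min-max scaling
  (scale-free, so volume-like features do not dominate by units).

**Commensuration.** Scores from heterogeneous rankers are not comparable,
and how the original consensus averaging made them comparable is not
something one can recover from a score plot; we orient every ranker to
higher-is-better (negating lower-is-better scores), min-max normalize each
to [0, 1] (a constant ranker maps to all 0.5 with a warning, i.e. it
abstains), and take the unweighted mean. A rank-average mode
(`method = "rank"`) is available as the obvious alternative. Ties in the
final consensus break by ascending feature name — deterministic and
reproducible. With a single ranker both modes reduce to that ranker's own
ordering.

**Signature.** From the top 25 consensus entries we take the
highest-ranked shape feature and the highest-ranked texture feature. Shape
and gray-level texture describe complementary aspects of a nodule, which
is what justifies treating the pair as quasi-independent covariates; if
the top-25 head contains no shape (or no texture) feature, selection fails
with an explicit error rather than silently reaching further down the
list. Signatures are labeled only by their feature content, never by which
selection group produced them.

# The likelihood functional forms

Two published forms are built in with their exact printed coefficients
(`pretrainedModel()`):

* **MLF I** (x1 = tumor volume in mm³, x2 = large-area low-gray-level
  emphasis):
  y = a + b·ln(x1) + c·ln(x1²) + d/x2 + e/x2² + f/x2³ + g/x2⁴,
  residual SE 0.30.
* **MLF II** (x1 = surface-to-volume ratio, x2 = GLCM sum entropy):
  y = a + b·x1 + c·x1² + d·x1³ + e·x1⁴ + f·ln(x2), residual SE 0.20.

Three design points deserve emphasis:

* **The ln(x1²) term is taken literally**: ln(x1²) = 2·ln(x1), so MLF I's
  basis is exactly collinear and only the combination b + 2c is
  identifiable. The printed coefficients belong to the printed form, so
  the pretrained model always uses this reading; a `squaredLog = TRUE`
  variant fits (ln x1)² instead, since a squared-log term is a plausible
  alternative reading of the notation.
* **Fitting is ordinary least squares on the basis expansion.** Both forms
  are linear in their coefficients, so OLS *is* the minimum-residual
  solution; no link function is applied to the 0/1 response (the forms are
  regression surfaces, not logistic models). The solver is the SVD
  pseudoinverse: on a rank-deficient design it returns the minimum-norm
  coefficient vector, predictions are invariant to the deficiency, and
  `residualSE` uses sqrt(RSS/(n − rank)). The convention behind the
  published 0.30/0.20 standard errors is not recoverable, so refits report
  this stated convention and make no claim of matching those two numbers.
* **Domains are enforced, not clamped**: x1 ≤ 0 under MLF I or x2 ≤ 0
  under either form raises an error at prediction time. A `clipEps` floor
  is available for pipeline robustness, but silently clamping by default
  would hide unit errors.

# Evaluation conventions

Classification is y ≥ 0.51 → malignant, with the boundary inclusive
exactly as published. The metric block exposes **both** naming
conventions: `paperSensitivity` = TP/(TP+FP) and `paperSpecificity` =
TN/(TN+FN) reproduce the numbers the source models report under the names
"sensitivity" and "specificity", while `stdSensitivity` = TP/(TP+FN) and
`stdSpecificity` = TN/(TN+FP) are the standard epidemiological
definitions. The two conventions disagree whenever FP ≠ FN, and exposing
only one of them would either fail to reproduce the published numbers or
mislead an epidemiologist, so the report names both explicitly. Ratios
with zero denominators are NA with a warning (e.g. any specificity on an
all-malignant detection cohort); an all-zero confusion matrix errors.

The ROC sweeps the rule y ≥ t over the distinct observed scores with tied
scores grouped into a single step, and the AUC is the trapezoidal
integral, which is provably the Mann–Whitney pair-counting statistic with
ties counted 1/2 — the test suite asserts that identity to 1e-12 and
cross-checks against pROC. Confidence intervals are out of scope: the
interval method behind the published CIs is unstated, and guessing one
would manufacture false precision.

# The synthetic cohort generator

`simulateCohort()` emulates the *structure* of a lung-nodule training
cohort so that every stage is testable without any imaging data: 105
features in the canonical class layout (shape 13, GLDM 14, GLCM 23,
NGTDM 5, first-order 18, GLSZM 16, GLRLM 16), a default class balance of
165 malignant / 35 benign, and four planted informative features — two
shape, two texture — each with standardized class-mean separation equal to
`effectSize` (default 2):

* `shape_Volume`: log-normal, benign median 270 mm³ (an 8 mm sphere,
  matching typical benign nodule diameters), sdlog 0.5, malignant shifted
  up by `effectSize` on the log scale. The separation contract holds on
  the log scale; on the raw scale the separation is somewhat smaller
  because of the heavy tail.
* `shape_SurfaceVolumeRatio`: truncated normal, sd 0.15, classes
  separating **symmetrically** about 0.9 (benign above, malignant below).
  The symmetric placement is deliberate: the pretrained MLF II surface
  crosses y = 0.51 near SVR ≈ 0.85 at typical sum-entropy values, and a
  generator meant to emulate cohorts on which that published model is
  applicable must move both classes away from that operating point as the
  separation grows. With a one-sided shift the benign class would sit on
  the decision boundary at every effect size and no degree of separation
  would ever be classifiable — a property of the generator, not of the
  model.
* `glcm_SumEntropy`: truncated normal, benign mean 3.5, sd 0.4, malignant
  shifted up (more heterogeneous texture).
* `glszm_LargeAreaLowGrayLevelEmphasis`: truncated normal, benign mean
  150, sd 40, malignant shifted up.

All remaining features are i.i.d. standard normal, independent of the
label; an optional `noiseCorrelation` knob equicorrelates them for
redundancy-ranker studies. `simulateRetest()` adds Gaussian noise with sd
= `retestNoiseSd` × the per-feature sd; two replicates of the same latent
table have theoretical per-feature CCC = 1/(1 + sd²), which the tests use
as a closed-form oracle. `simulateFromModel()` draws (x1, x2) uniformly
inside a form's domain and evaluates the model, supporting exact
parameter-recovery tests.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: realistic inter-feature covariance (real
radiomic features are strongly correlated in blocks), non-Gaussian noise
marginals, scanner/protocol batch effects, segmentation variability, and
any relationship between the noise features and the planted ones. Results
on synthetic cohorts demonstrate the algorithms' correctness and their
behavior under a controlled signal, not clinical performance.

# Numerical choices and degenerate inputs

* Feature values must be finite; CSV cells that do not parse as numbers
  error with the offending row and column named.
* Constant features: Kruskal–Wallis p = 1 (warning); ReliefF weight 0;
  MI 0; variance 0; redundancy correlation treated as 0 (warning);
  Laplacian/SPEC assigned the worst score (warning). Infinite ranker
  scores are replaced by the maximal finite score + 1 so min-max
  normalization stays defined.
* Heat-kernel edge weights are floored at exp(−700) (see above).
* Consensus ties break by feature name; kNN-distance ties break by sample
  index; both make every ordering deterministic.
* All simulation functions take an explicit integer seed and are
  bit-reproducible given seed plus configuration; the pipeline derives
  every stage's randomness from the single config seed.

# Problem sizes in the test suite

The suite exercises the stochastic claims at sizes chosen to keep the
binomial/Monte-Carlo error well below the asserted margins: Kruskal–Wallis
type-I calibration over 500 null cohorts of n = 40; the CCC closed form on
500-sample cohorts; signature recovery over 100 cohorts of 100 + 100
samples at effect size 3 (both ranker groups must place the planted pair
first among their kinds); AUC/Mann–Whitney identity on dozens of random
tied instances at machine precision.

# Known limitations

* The ranker bank is a representative subset, not a reproduction of any
  specific historical set of thirteen algorithms; consensus orderings will
  differ from pipelines using other banks.
* Refitted residual standard errors follow the sqrt(RSS/(n − rank))
  convention and are not comparable to published values computed under an
  unknown convention.
* The published models' reported external performance (lung AUCs,
  retained-feature counts on specific cohorts) depends on the original CT
  datasets and cannot be recomputed from feature tables the package
  generates; the package reproduces the printed *derived* quantities
  (metrics from confusion matrices, detection rates, coefficient
  evaluations) exactly, and validates the data-dependent machinery by
  property-based simulation instead.
* No multiple-testing correction in the screen and no confidence
  intervals on metrics or coefficients, by design (see above).
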