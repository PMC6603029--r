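# radiolik

Radiomics-driven likelihood functions for CT tumor classification.

`radiolik` is for researchers who have a table of radiomic features — shape
and gray-level texture statistics computed from segmented CT tumors — and
want to (1) screen the features for test–retest reliability and class
discriminability, (2) rank them by consensus over a bank of supervised and
unsupervised ranking algorithms, (3) distill a two-feature diagnostic
signature (one shape + one texture feature), and (4) classify tumors with
closed-form *likelihood functions* of that signature. The package ships
the two published functional forms with their exact coefficients and can
refit the same forms to new cohorts. No image processing happens here:
input is a CSV with one row per nodule and PyRadiomics-style feature
columns.

## The models

A likelihood function maps a signature pair (x₁, x₂) to a score y, with
y ≈ 1 meaning malignant and y ≈ 0 benign; a nodule is called malignant
when y ≥ 0.51. Two forms are built in:

**MLF I** — x₁ = tumor volume (mm³), x₂ = large-area low-gray-level
emphasis (GLSZM):

    y = a + b ln(x₁) + c ln(x₁²) + d/x₂ + e/x₂² + f/x₂³ + g/x₂⁴

**MLF II** — x₁ = surface-to-volume ratio (shape), x₂ = sum entropy
(GLCM):

    y = a + b x₁ + c x₁² + d x₁³ + e x₁⁴ + f ln(x₂)

`pretrainedModel("MLF1")` / `pretrainedModel("MLF2")` carry the published
coefficients at full precision. `fitLikelihood()` refits either form by
least squares on the basis expansion (the minimum-RSS solution, computed
with the SVD pseudoinverse — MLF I's printed basis is exactly collinear,
since ln(x₁²) = 2 ln(x₁), and the pseudoinverse handles that cleanly).

Upstream of the models, the screening stage uses Lin's concordance
correlation coefficient (CCC > 0.85 across repeat scans) and the
Kruskal–Wallis test (p < 0.05 against the malignancy label); the ranking
stage averages min-max-normalized scores from Fisher score, ReliefF and
mutual information (supervised group) or Laplacian score, SPEC, minimum
redundancy and min-max variance (unsupervised group). See the methods
vignette (`vignettes/radiolik-methods.Rmd`) for every formula and design
decision.

## Worked example

End-to-end on a synthetic cohort (165 malignant / 35 benign, 105 features,
four planted informative features at standardized separation 3):

```r
library(radiolik)

cohort <- simulateCohort(nMalignant = 165, nBenign = 35,
                         effectSize = 3, seed = 42)
cohort
#> RadiomicsExperiment: 200 samples x 105 features
#>   classes: shape(13) firstorder(18) glcm(23) gldm(14) glszm(16) glrlm(16) ngtdm(5)
#>   labels: 165 malignant / 35 benign

retest <- simulateRetest(cohort, retestNoiseSd = 0.3, seed = 43)
screen <- reliabilityFilter(cohort, retest = retest,
                            cccMin = 0.85, alpha = 0.05)
screen
#> ReliabilityReport: 105 features, 7 retained
#>   gates: CCC > 0.85, Kruskal-Wallis p < 0.05
```

All 105 features are reliable at this retest noise level, so the screen is
driven by discriminability: the 4 planted features survive, plus 3 noise
features that pass the 5% test by chance (no multiplicity correction, by
design). Ranking and signature selection:

```r
ranking <- rankFeatures(cohort[retainedFeatures(screen), ],
                        group = "supervised")
sig <- selectSignature(ranking, cohort, topK = 25)
sig
#> RadiomicSignature [supervised]: shape = shape_SurfaceVolumeRatio,
#>   texture = glszm_LargeAreaLowGrayLevelEmphasis

v <- featureValues(cohort)
fit <- fitLikelihood("MLF2", v[, shapeFeature(sig)],
                     v[, textureFeature(sig)], sampleLabels(cohort),
                     x1Feature = shapeFeature(sig),
                     x2Feature = textureFeature(sig))
ev <- evaluateScores(predict(fit, cohort), sampleLabels(cohort),
                     threshold = 0.51)
ev
#> EvalReport: TP 165  FN 0  FP 2  TN 33
#>   accuracy 0.9900 | sensitivity TP/(TP+FP) 0.9880 | specificity TN/(TN+FN) 1.0000
#>   std sensitivity 1.0000 | std specificity 0.9429 | AUC 0.9997
```

The report prints both metric conventions: `sensitivity TP/(TP+FP)` and
`specificity TN/(TN+FN)` are the aliases under which the source models
report their numbers, `std *` the standard epidemiological definitions.
Feeding in the published MLF II lung confusion matrix reproduces its
printed metrics:

```r
evalReport(tp = 161, fn = 4, fp = 2, tn = 33)
#> EvalReport: TP 161  FN 4  FP 2  TN 33
#>   accuracy 0.9700 | sensitivity TP/(TP+FP) 0.9877 | specificity TN/(TN+FN) 0.8919
#>   std sensitivity 0.9758 | std specificity 0.9429 | AUC -
```

The same workflow is scriptable: `inst/scripts/radiolik.R` exposes
`simulate`, `filter`, `rank`, `signature`, `fit`, `predict`, `evaluate`
and `run` (full pipeline from a YAML config) subcommands, and
`runPipeline()` drives everything from one seed with per-stage artifacts.

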