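---
title: "Local hyperplane nearest-neighbor classification of small clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local hyperplane nearest-neighbor classification of small clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(khknn)
```

## The problem

Predicting cerebrovascular risk in end-stage renal disease cohorts is a
small-sample, imbalanced, mixed-type tabular problem: tens of patients,
dozens of predictors spanning demographics, comorbidity flags, blood
chemistry, mineral-bone-disorder markers (FGF23, klotho, fetuin-A),
nutritional indices and calcification scores, and a binary risk-group
label derived from clinical stroke scores. Flexible models overfit at
this scale, and plain k-nearest-neighbor classification is notoriously
sensitive to the choice of k. The local hyperplane family addresses both:
it enriches each class's representation near the query from k isolated
points to their affine hull, and it damps that enrichment with a ridge
penalty.

## Model and assumptions

For a query $x$ and class $c$, let $N_1^c,\dots,N_k^c$ be the k nearest
class-$c$ training points (Euclidean distance in input space), with
centroid $\bar N_c$ and centered differences $V_i^c = N_i^c - \bar N_c$.
The fitting objective is

$$\big\|x - \bar N_c - \textstyle\sum_i \alpha_i V_i^c\big\|^2
  + \lambda \|\alpha\|^2 ,$$

minimized in closed form by $(V V^\top + \lambda I)\,\alpha = V(x - \bar
N_c)$. The class decision uses the squared *residual* only — the
$\lambda\|\alpha\|^2$ term regularizes the fit but does not enter the
distance being compared across classes. Both quantities are stored
(`objective_value` vs `decision_distance_sq`).

The kernelized variant forms $\bar x = x - \bar N_c$ and the $V_i^c$ in
input space *first*, and only then maps them through the kernel:

$$\alpha = (K(V,V) + \lambda I)^{-1} K(V,\bar x), \qquad
  d^2 = K(\bar x,\bar x) - 2\alpha^\top K(V,\bar x)
      + \alpha^\top K(V,V)\,\alpha .$$

Centering before mapping is part of the model definition, not an
approximation: it is *not* equivalent to centering in feature space, and
the implementation deliberately does not "correct" it. Neighbor selection
likewise stays in input space on both paths; re-ranking neighbors by the
kernel-induced metric is a different (undefined here) model and is not
implemented.

With the linear kernel the two paths coincide: $K(V,V) = VV^\top$ and the
kernel solve reproduces the linear solve to floating-point accuracy. This
equivalence is the suite's strongest internal consistency check, asserted
over hundreds of random instances.

Useful limits, all asserted as tests:

* $k = 1$: $V_1^c = 0$, so $\alpha$ vanishes and the decision distance is
  exactly the squared distance to the class's nearest neighbor —
  per-class 1-NN.
* $\lambda \to \infty$ (linear path): distances tend to
  $\|x - \bar N_c\|^2$, a local-centroid classifier.
* $\lambda \to \infty$ (RBF path): every class distance tends to
  $K(\bar x, \bar x) = 1$ and the classifier is uninformative — a
  documented degeneracy, not a bug; it is why $\lambda$ is held at a
  moderate fixed value rather than tuned upward.

## Parameters

* **k** (neighbors per class): default grid 2–8, step 1. If a class has
  fewer than k members — routine under leave-one-out on a 25/34 cohort —
  k is capped at the class size and the effective value recorded.
* **gamma** (RBF bandwidth, dimensionless): default grid $2^{-5}$ to
  $2^5$ in multiplicative steps of $2$, i.e. 11 values; with k's 7 values
  this is the 77-configuration grid. `gamma = 0` is rejected: the
  constant-1 limit degenerates the Gram system.
* **lambda** (ridge penalty): fixed at 1 by default for robustness on
  small cohorts, exposed as an override; the kernel path requires
  $\lambda > 0$ so the regularized Gram system is nonsingular.
* **standardize**: on by default. Local-distance methods are
  scale-sensitive (a constructed test shows a 1000-fold rescaling of one
  column flipping a prediction), so continuous columns are centered and
  scaled; binary columns pass through. Under the jackknife the statistics
  are refitted on each fold's n−1 training rows — held-out rows never
  leak into the scaling.

## Evaluation protocol

Evaluation is leave-one-out (jackknife): each sample is predicted by a
model built on the remaining rows, and the n pooled predictions form one
confusion matrix with seven metrics — accuracy, sensitivity, specificity,
precision, NPV, F-score and MCC. High-risk patients are the positive
class. Any metric whose defining denominator is zero is `NaN`, never
silently 0: an all-positive predictor legitimately reports SN = 100%,
Spec = 0%, NPV = NaN, MCC = NaN, and the NaN propagates to the report.
Metrics are stored as fractions; percentages appear only at the
formatting boundary. The MCC denominator is factored into four square
roots so large counts cannot overflow.

Grid search selects by MCC — accuracy is misleading at a 25/34 imbalance
— with NaN configurations ineligible, and ties broken toward smaller k,
then smaller gamma (the simpler, smoother model). Grid evaluation order
is immaterial to the result.

## The synthetic cohort generator

The study cohort this package models is summarized publicly only as
per-feature means ± SDs (or category counts) and Pearson correlations
with the risk label. `default_cohort_spec()` transcribes that summary: 32
mixed features, n = 59, and a fixed 25/34 label split (fixed, not
Bernoulli, because leave-one-out behavior depends on the realized
counts). Generation uses a single latent factor: with $s$ the
standardized label and $\varepsilon$ standard normal,
$z = r\,s + \sqrt{1-r^2}\,\varepsilon$; continuous features map $z$
affinely to the target mean/SD, binary features threshold $z$ at the
Gaussian quantile of the target proportion.

What this emulates: marginal locations, scales, proportions and each
feature's association with the label. What it does not: feature–feature
correlation (no published joint structure exists to target), point-mass
or skewed marginals, and the exact point-biserial attenuation of binary
features (the generator targets the latent $r$; the realized correlation
of a thresholded feature is attenuated by roughly the factor
$\phi(q)/\sqrt{p(1-p)}$, documented rather than corrected). Passing tests
on synthetic cohorts therefore demonstrate protocol correctness and
calibration of the machinery, not clinical performance: a synthetic
replicate is *harder* than the real cohort, whose risk factors
co-vary.

Two generator choices were genuinely open and are worth recording:

* Heavy-tailed assay quantities (C-reactive protein, FGF23, IL-6 have
  SD > mean) are generated as Gaussians from the published moments, and
  negative draws are **kept** by default. Clamping at zero is available
  (`floor_at_zero = TRUE`) but biases the realized mean upward by several
  tenths of an SD for exactly those features, violating the generator's
  moment-recovery contract; preserving the targeted moments was judged
  more important than sign realism for a classifier benchmark.
* For binary features with tiny target correlations (e.g. $|r| \approx
  0.003$) the empirical sign is statistically indistinguishable from
  noise even at n = 10⁴ (SE ≈ 0.01), so sign recovery is only asserted
  where $|r| \ge 0.1$; the magnitude bound $|\hat r| \le |r| + 0.05$ is
  asserted everywhere.

Fidelity tests run at n = 10⁴ (moments within 0.05·SD, proportions
within 3 binomial SEs, continuous-feature correlations within ±0.05);
classifier sanity tests use two 5-D Gaussian blobs, 200 samples, centers
6 SDs apart (accuracy ≥ 0.95 expected) or coincident (chance). These
sizes keep the whole suite under a minute per block while leaving
comfortable statistical margins.

## Numerical choices

* Coefficient systems are solved by Cholesky factorization of
  `Gram + lambda I` (never an explicit inverse), with one
  iterative-refinement step if the residual exceeds 1e-10.
* At $\lambda = 0$ the linear system can be rank-deficient (duplicate
  neighbors); it is then solved in the minimum-norm sense via the SVD and
  flagged `singular`.
* Kernel decision distances can go slightly negative by cancellation;
  they are clamped at 0.
* RBF evaluations compute $\|a-b\|^2$ from the difference vector
  directly, avoiding the $\|a\|^2+\|b\|^2-2a^\top b$ expansion whose
  cancellation can produce negative squared distances.
* Ties: neighbor ties by ascending training-row index; class-distance
  ties toward the smaller class id; grid MCC ties toward smaller k, then
  smaller gamma. All deterministic.

## Feature-set default

When a cohort has the default roster shape, the CHADS2 and CHA2DS2-VASc
columns are excluded from the predictors by default
(`default_excluded_columns()`): the risk-group label is defined from
those scores, so including them leaks the label. The exclusion is
overridable for users who want the leak deliberately (e.g. to bound
achievable performance).

## Clinical scores

CHADS2 (0–6): one point each for congestive heart failure, hypertension,
age ≥ 75, diabetes; two for prior stroke/TIA. CHA2DS2-VASc (0–9): one
point each for CHF, hypertension, diabetes, vascular disease, female sex,
age 65–74; two each for age ≥ 75 and prior stroke/TIA, the age bands
mutually exclusive. Scores 0–1 are the low-risk group, ≥ 2 high-risk. The
age-75 boundary is implemented as ≥ 75 throughout. GNRI is
$14.89\,\mathrm{albumin(g/dl)} + 41.7\,\mathrm{(weight\ ratio)}$; because
laboratories often report albumin in g/L, values above 10 g/dl trigger a
unit-confusion warning and a converter is provided. Ideal body weight has
no universal formula and is an input, not computed. The AACS bands each of
eight aortic wall segments (anterior/posterior × L1–L4) by calcified
length fraction — 0: none; 1: < 1/3; 2: 1/3–2/3; 3: > 2/3 — and sums to
0–24. The verbal band definitions leave the boundary fractions open;
exactly 1/3 and 2/3 are assigned to the middle band (closed middle
interval), a choice tests pin down explicitly.

## Known limitations

* Instance-based: there is no fitted model object to serialize; the
  "model" is the training table plus configuration, and prediction cost
  grows with the training set (no tree-based neighbor index is built).
* Binary-feature correlations are attenuated by thresholding, so
  synthetic cohorts under-represent the printed associations of binary
  risk factors.
* Multi-class inputs are supported by the core, but the metric suite and
  protocols are binary (positive vs negative class).
* Performance numbers obtained on synthetic replicates do not transfer
  to the original cohort; they validate the machinery only.
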