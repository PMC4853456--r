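---
title: "Methods: tract-restricted multivariate analysis of DTI metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-restricted multivariate analysis of DTI metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractmvpa)
```

## The problem this package addresses

Group differences in white-matter microstructure after repeated concussion
are often too subtle for voxelwise univariate tests, yet a multivariate
classifier reading *all* voxels of a single tract at once can separate
groups reliably. `tractmvpa` implements that analysis for diffusion-tensor
metrics (FA, MD, AD, RD) restricted to a tract skeleton — the uncinate
fasciculus connecting orbitofrontal cortex and the anterior temporal lobe is
the motivating tract — together with the machinery needed to trust such a
result: full-pipeline permutation significance, null ROC contour bands,
interpretable voxel-group covariance maps with TFCE inference, bootstrap
coefficient maps, and the univariate behavioural layer (go/no-go response
inhibition, questionnaire scores, tract-behaviour correlations, ROI-pair
functional connectivity).

Because no subject MRI data are distributable, the package ships a
first-class synthetic-data module. Every stage is tested against that
generator or against independent oracles.

## The synthetic cohort generator

**Geometry.** `make_skeleton()` voxelizes a cubic Bezier curve into a
connected tube of exactly `n_voxels` 1-mm voxels (26-neighbour adjacency),
with `end_fraction` of the voxels labelled `frontal` and `temporal` at the
two ends by rank along the arc. Default sizes (940 right, 832 left) follow
the study tract sizes.

**Metrics.** Per voxel the eigenvalue triple is constructed as
`lambda1 = AD`, `lambda2 = RD (1 + s)`, `lambda3 = RD (1 - s)` with split
`s = 0.3`, so `RD = (lambda2 + lambda3)/2` and `MD = (AD + 2 RD)/3` hold
exactly, and FA follows the standard tensor formula
`FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`
(the source study never prints the FA formula; this is the conventional
definition). Baselines `AD = 1.2e-3`, `RD = 0.55e-3` mm^2/s are conventional
healthy white-matter skeleton magnitudes, not values from the study.

**Noise.** Each subject receives a global offset (SD `sd_subject`, default
`2e-5` mm^2/s) plus a spatially smooth field: iid Gaussian noise smoothed
along the skeleton graph with an exponential kernel (`exp(-d/decay)`,
`decay = 5` voxels), rows scaled to unit norm so the per-voxel SD is
`sd_voxel` (default `2e-5`). Fields are truncated at 5 SD so diffusivities
remain positive; amplitudes that would break positivity anyway raise an
error. The study reports no within-group variance for any metric, so these
levels are a package choice: they put a 3-SD effect at the edge of
univariate detectability, the regime the study describes.

**Effect.** The implanted group effect follows a signed field that is +1 at
the frontal-end centre, -1 at the temporal-end centre, and tapers as a
Gaussian in arc position (`taper = 0.15`): athletes get higher MD frontally
and lower MD temporally, the spatial pattern reported for the right
uncinate. With `metric = "MD"` the shift is added equally to AD and RD so
the MD group difference equals the amplitude exactly. The default amplitude
`6e-5` mm^2/s is three voxel-noise SDs — the "detectable by MVPA, marginal
univariately" condition used throughout the tests.

**Behaviour.** The SART schedule is the published design: 9 digits x 25
repetitions, 250 ms stimulus + 900 ms ISI (1.15 s pacing, 225 trials,
about 4.3 min), no-go exactly on digit 3. Response models are binomial for
commission errors and truncated-Gaussian for RT. Default group parameters
(athletes 295 +/- 35 ms vs controls 340 +/- 35 ms; commission 0.40 vs 0.16;
aggression 58 vs 47, mania 55 vs 46, SD 8) give roughly 1-2.4 SD
separations, mirroring the qualitative behavioural findings at n = 19 vs
17; the weakest (mania) has about 90% single-cohort power, which the tests
accommodate by majority vote over replicate cohorts.
`simulate_behaviour_scores()` can instead tie any score to a tract summary
at an exact population correlation (used to emulate the reported
AD-aggression association of about -0.54).

**Reproducibility.** One cohort seed fans out to per-subject streams via a
counter-based scheme (`seed * 1000003 + counter * 7919` mod 2^31), so any
subject — and the whole cohort — regenerates bit for bit.

**What the generator does not emulate.** Registration error, partial-volume
effects, skeleton projection artefacts, heteroscedastic or non-Gaussian
noise, site effects, and any realistic FA-MD dependence beyond what the
eigenvalue construction induces. Passing tests therefore demonstrate the
*statistical machinery* is correct and calibrated, not that real concussion
data would yield the study's accuracies.

## Tract-map post-processing

Probabilistic tract maps are normalized by the way-total (counts /
way-total) and thresholded at a fraction of the 95th percentile of the
within-tract intensity distribution — 0.20 for the uncinate, 0.40 for the
SLF control tract. Three conventions are fixed and documented because
retained-voxel counts depend on them: the percentile uses linear
interpolation between order statistics (`quantile` type 7); it is computed
over strictly positive voxels only (background zeros are not part of the
tract distribution); and retention is closed (`>=`, ties kept). Whether the
study averaged subject maps before or after thresholding is ambiguous; both
orders are available to callers, and the scripts threshold per map.
Skeleton intersection returns voxels in lexicographic coordinate order.

## Feature selection

Within each training fold, each voxel gets the two-class F-score
`[(m+ - m)^2 + (m- - m)^2] / (s+^2 + s-^2)` (class sample variances, n-1
denominator) and the top `ceiling(fraction * V)` voxels are kept — ceiling
so a positive fraction never selects zero voxels; ties break to the lower
voxel index. The cited F-score leaves both-class-constant voxels undefined:
the package scores them 0 when the class means agree and infinity when they
differ. The candidate fractions searched by the study's grid are unstated;
{0.01, 0.05, 0.1, 0.25, 0.5, 1} are package defaults.

## Classifiers

**Kernel SVM.** Soft-margin C-SVC with linear, polynomial (degree 3,
coef0 = 1 — the degree is unstated in the study) and RBF kernels, solved by
a compact maximal-violating-pair SMO on the dual (tolerance 1e-5). The
solver is cross-checked in the tests against an independent libsvm fit. A
fused C++ leave-one-out path evaluates the whole (fraction x C x gamma)
grid per fold, which is what makes 10^5-fold permutation workloads
affordable on one CPU.

**ElasticNet logistic regression.** Minimizes mean logistic loss +
`lambda1 [alpha ||b||_1 + (1-alpha)/2 ||b||_2^2]` (intercept unpenalized)
by FISTA with gradient-based adaptive restart; step from the spectral norm
of the design. Tests verify the objective against glmnet and a generic
convex solver to 1e-6.

**Total-variation logistic regression.** Adds
`lambda_tv * sum_edges |b_u - b_v|` over skeleton adjacency edges —
anisotropic TV, which keeps the ADMM z-update an elementwise
soft-threshold; the isotropic variant of the cited method is noted as an
alternative. ADMM splits `z1 = b`, `z2 = D b`; the smooth beta-step is an
L-BFGS-B solve with warm starts; rho starts at 1 with residual-balancing
updates; iteration cap 5000. Exit tolerances are `eps_abs = 1e-9`,
`eps_rel = 1e-7`: tighter than the 1e-6/1e-4 one might use for exploratory
fits, because the package asserts coefficientwise agreement (1e-4) with the
pure-lasso ElasticNet in the `lambda_tv -> 0` limit, and that requires both
solvers near their common optimum. The reported coefficients are the
consensus variable `z1`, which carries the exact sparsity. The true
objective evaluated along ADMM iterates is *not* monotone (transient
increases of order 1e-4 occur); the trace is stored for diagnosis, and
optimality is asserted at exit against the convex oracle instead.

**Conventions shared by all families.** Features are z-scored per voxel
with training-fold mean/SD, applied unchanged to test subjects (the study
is silent on standardization; it is the default and can be disabled).
Higher decision score means more athlete-like (+1); a score of exactly zero
predicts +1.

## Cross-validation, grid search and permutation inference

`loocv()` holds out one subject per fold; F-scores, selection and
standardization are computed from the training subjects only (the
acceptance suite probes this no-leakage property directly). By default,
hyper-parameters are chosen by maximizing the *same* LOOCV accuracy that is
reported — the optimistic protocol the study describes. The reported
accuracy is therefore biased upward, but the permutation test repeats the
identical procedure (selection, training, grid search) under permuted
labels, so the p-value remains valid. A fully nested mode
(`nested = TRUE`) is available when an unbiased point estimate matters.

Permutations are uniform random relabelings (preserving class sizes);
significance is the fraction of permutations with performance equal or
superior to the correct labelling — the raw fraction, which can be 0,
matching the study's printed style; the `(b+1)/(m+1)` estimator is reported
alongside. The statistic defaults to accuracy with AUC selectable. The
study's 10,000 permutations are a scale choice; the package default is 500
at desk scale, and the permutation pass re-runs whatever grid the observed
run used (callers wanting the study's full-resolution grid under
permutation simply pass it).

ROC curves pool the held-out decision scores across folds (per-fold
averaging is an option); the trapezoidal AUC equals the Mann-Whitney pair
statistic with ties counted 1/2, verified exhaustively in the tests. Null
ROC contour bands interpolate each null curve onto an FPR grid and take
pointwise inverse-ECDF quantiles: the contour at level p is the (1-p)
quantile, so smaller p gives higher, nested contours.

## Spatial maps and TFCE

The covariance map is the per-voxel sample covariance (n-1 denominator)
between feature values and the -1/+1 group coding — the interpretable
"activation pattern" for a two-group design; the n denominator would only
rescale it. TFCE integrates `extent^E * h^H * dh` over thresholds with
E = 0.5, H = 2, dh = max/100 — the conventions of FSL randomise, which the
study delegated to; they are inherited defaults, not study text. Signed
maps are handled by enhancing the positive and negated maps separately and
re-signing. FWE inference uses the permutation distribution of the maximum
|TFCE|, with the unpermuted labelling included in the null ensemble, so
p-values lie in [1/n_perm, 1].

Bootstrap coefficient maps resample subjects with replacement, keep
hyper-parameters fixed at the supplied (full-data) values — re-optimizing
per resample would change the estimand and is computationally
disproportionate — redraw resamples that lose a class (counted), and
average raw-scale coefficients. Diagnostics (sign agreement and Pearson r
between coefficient and covariance maps) are computed over the non-zero
coefficient support.

## Behavioural statistics

Group comparisons use the pooled-variance Student t (the study states a
plain two-sample t-test; Welch is an option). Correlations are Pearson,
with age-partialled variants computed both by the first-order formula and
by residual correlation (the two routes agree to 1e-10 in tests; df =
n - 3). The exploratory correlation battery is reported at uncorrected
p < 0.05 two-tailed, as in the study; a Benjamini-Hochberg column is
produced alongside for transparency. ROI-pair connectivity is Pearson r
with its Fisher z (`atanh`), and the group comparison of connectivity is
done on z by default (the study does not say; z is the variance-stabilized
choice).

## Numerical choices and degenerate inputs

Ties in selection break to the lower voxel index; sign ties in prediction
go to +1; the percentile convention is type 7; zero-variance voxels pass
through standardization with SD 1; all-zero coefficient maps yield an
explicit empty diagnostics result; |r| = 1 maps to an infinite Fisher z
with a warning; way-total 0, all-zero tract maps, empty voxel lists,
single-class folds and mismatched grids/affines raise typed errors. Every
stochastic routine takes an integer seed, and derived streams stay inside
32-bit range.

## Problem sizes used by the tests and acceptance script

The suite exercises the study-scale geometry (900-940 voxels, 19 vs 17
subjects) for signal recovery and the spatial maps, 200 replicate null
datasets of 10 vs 10 x 50 voxels with 200 permutations each for the
calibration check, and 500 permutations elsewhere — sizes chosen so the
whole suite completes comfortably on a single CPU while keeping every
check at full pipeline fidelity. The acceptance script reports, among other
quantities, the SART design constants, LOOCV accuracy/AUC and permutation
p on the default cohort, end-region sign agreement at n = 200 per group,
the minimum TFCE FWE p, bootstrap coefficient-covariance diagnostics, and
the recovered behavioural correlations.

## Known limitations

The TV penalty is anisotropic; the ADMM objective trace is non-monotone
(see above); `make_skeleton()` targets tube-like tracts only; the
generator's noise model is stationary Gaussian; LOOCV is the only
cross-validation scheme (by design); and reported accuracies on synthetic
data say nothing quantitative about real cohorts — the study's headline
numbers were computed on unavailable subject data and are mirrored here in
table layout only.
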