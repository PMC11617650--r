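---
title: "Engineered enviromic markers and reaction-norm ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineered enviromic markers and reaction-norm ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reemtools)
```

## The problem

Multi-environment trial (MET) networks in plant breeding phenotype a set of
hybrids at a limited number of locations, yet recommendations are needed for
every farm in the target population of environments (TPE). Two obstacles
stand between the trial data and a per-location recommendation map:

1. The environment is observed through hundreds to thousands of raw
   covariates (satellite reflectance, climate normals, daily weather, soil
   profiles) that are strongly collinear and individually weak predictors.
2. Genotype-by-environment interaction (G x E) means the ranking of hybrids
   changes across the TPE, so a single national ranking wastes most of the
   information the trial network paid for.

`reemtools` addresses both with a two-stage pipeline. Stage one compresses
the covariate stack into a handful of *engineered enviromic markers* (EEMs)
— one-dimensional environmental gradients learned by a regression-tree
ensemble that predicts trial mean yield. Stage two fits a random-regression
reaction-norm mixed model on those markers with a pedigree covariance, and
everything downstream (yield surfaces, stability angles, breeding zones,
per-bin recommendations, parental picks) is derived from that fit.

## The prediction grid

The TPE is discretized into square bins. The trial points are projected to
planar km with a local equirectangular projection about their centroid
(adequate at regional extents of a few hundred km), the convex hull of the
points is dilated by a buffer (default 50 km), and a regular lattice of
cells (default 5 km, i.e. 25 km^2 bins) anchored at the buffered bounding
box minimum covers it. A bin is kept when its centroid lies within the
dilated hull; dilation is Euclidean, so the region has rounded corners.
Membership by centroid (rather than cell overlap) is the simplest defensible
reading of bins "covering" the buffered polygon; because the lattice anchor
derives only from the point set's bounding box, the construction is
invariant to point order and to whole-cell translations.

## Stage one: engineering enviromic markers

For each of `n_trees` trees (study-scale default 10 000):

* draw a random genotype subsample (default fraction 0.5 — the procedure
  only requires "randomly selected genotypes", and half the census keeps
  each bootstrap mean informative while still varying the genotype set);
* recompute each trial's environment mean `m` over the subsample, topping
  up trials where fewer than two sampled genotypes appear;
* draw a covariate subset of size `sqrt(p)` (the standard random-forest
  rule; no explicit `mtry` is prescribed by the method) and fit a CART
  regression tree of `m` on the subset over trials (`rpart`, depth
  unconstrained, minimum two trials per leaf — a small-n default).

The trees' prediction vectors over the grid are standardized and clustered
by average-linkage hierarchical clustering at correlation distance
`1 - r`, cut at `K` clusters (default `K = 7`). Correlation distance is the
natural choice because the markers are used as *gradients*: their scale is
removed by standardization anyway. The k-th marker is the mean of cluster
k's standardized predictions, re-standardized over the grid. The mean over
all trees gives a single "wide-environment gradient" used for plotting and
for the variance-gradient profile. The grid (not the trial set) is the
reference for clustering and standardization so markers are well scaled
where predictions are made. Marker engineering is validated by in-sample
correlation with observed trial means and by leave-one-trial-out refits
(with a reduced tree count per fold); the leave-one-out summary is the
Pearson correlation between observed and held-out-predicted means over the
trial set, since a per-trial correlation of a single held-out point is
undefined.

A note on an ambiguity: the source method speaks of 10 000 "predictors,
comprising N regression trees"; this package implements each predictor as a
single tree with `n_trees` configurable, which reproduces the aggregate
behaviour (forests are recovered at the cluster level).

The importance tally ("envirome-wide association study") ranks covariates
within each tree by impurity decrease — the CART-native importance — and
counts rank-1..5 occurrences across trees; per-source shares are normalized
mean importances.

## Stage two: the reaction-norm mixed model

With trial-level standardized BLUEs `y`, the model is

\[ y = Xb + Zu + e, \qquad u \sim N(0, \Sigma \otimes A), \qquad
   e \sim N(0, I\sigma^2_e), \]

where `X` carries one fixed intercept per year, `Z` is block-diagonal over
genotypes — each block a leading column of ones (overall genetic merit, as
in ordinary pedigree BLUP) followed by the K marker values of the record's
trial — `A` is the additive relationship matrix from the pedigree (tabular
method; genotypes with both parents unknown, the "competitor" hybrids, are
treated as unrelated non-inbred founders so `A` keeps full dimension), and
`Sigma` is the unstructured (K+1)-square covariance of intercept and
reaction-norm slopes.

REML estimation combines expectation-maximization steps on Henderson's
mixed-model equations — the residual update
`(y'y - b'X'y - u'Z'y)/(n - p)` and the coefficient-covariance update
`Sigma[r,s] = (u_r' A^{-1} u_s + tr(A^{-1} PEV_rs))/q` — with
average-information (AI) acceleration: each iteration computes the REML
scores and the AI matrix from the current MME factorization (the analytic
scores are verified against numerical gradients in development) and takes
a damped Newton step, accepted only when it does not decrease the REML
log-likelihood; rejected steps fall back to a SQUAREM-extrapolated pair of
EM updates, which ascend by construction. `Sigma` is bent to positive
definite (eigenvalue floor) after every proposal. Convergence is declared
when the relative log-likelihood change falls below `tol` (default 1e-8
for single fits, 1e-6 inside the ensemble); the iteration budget `maxit`
counts MME solves. When the
genotype count is small relative to the parameter count (`q < 5(K+1)`) an
unstructured `Sigma` is not reliably estimable and the fitter falls back to
a diagonal structure, with a message.

BLUPs for unphenotyped parents come out of the same equations through
`A`: parent coefficients are shrunken combinations of their descendants'.

### The ensemble

"Each run capturing one of the enviromic markers" is read as: per run, one
tree predictor is sampled from each of the K clusters, standardized with
the grid constants, and used as the K regressors (a one-marker-per-run mode
is available behind `one_marker_per_run = TRUE`, since the sentence admits
that reading too). Every run refits REML (warm-started from the previous
run) and predicts all genotypes at all bins; the ensemble reports the mean
surface, the run-to-run standard error, pooled `Sigma` (mean over runs) and
the slope draws. A run is dropped only when the fit fails numerically or
stops at the iteration cap with the log-likelihood still moving (relative
change above 1e-3); losing more than 20% of runs is an error. Bin
predictions use the mean of the fitted year intercepts ("typical year"),
since surfaces are drawn without reference to a particular year.

Stability/adaptability is summarized as angles: `atan(slope)` in degrees,
0 for a flat (stable) reaction norm, 45 for a strongly responsive one,
negative when yield falls along a rising gradient. Angles are pooled over
all sampled markers across runs, and genotype tables report min/max/mean.

### Comparator models

The *baseline* G x E model uses no covariates: irrigation as fixed,
genotype as random with covariance `A sigma_g^2`. With trial-level BLUEs
there is exactly one record per (trial, genotype), so an iid
trial-by-genotype interaction term is confounded with the residual and is
absorbed there; predictions for new trials are irrigation effect plus
genotype BLUP. The *kernel* model builds a linear environment kernel from
the same standardized EEM vectors (scaled to unit mean diagonal) and fits
genotype (A), environment, and interaction (elementwise product) variance
components by dense EM-REML; predictions at new locations use kernel
cross-covariances. At fixed variance components and a single marker the
kernel interaction model and the random-regression model are the same
model, which the test suite exploits as an internal cross-check.

## Breeding zones and recommendation

With `z(bin) = (1, eps_1..eps_K)'`, the additive genetic variance at a bin
is `z' Sigma z` and the genetic correlation between bins follows from the
same quadratic form; `Sigma` is the pooled ensemble estimate. The full
bin-by-bin matrix is never materialized — the surface object stores
`Z sqrt(Sigma)` and evaluates any entry lazily. Zones are Ward
agglomerations (`ward.D2` on `d = sqrt(2(1-r))`) over a subsample of bins
(default 2000, selected by sorted bin id so the partition is reproducible
and order-invariant); remaining bins join the nearest zone centroid in
marker space. Zone labels are ordered by descending mean predicted yield.
On the standardized yield scale the top-1 selection gain is reported as an
absolute difference — a percentage of a near-zero standardized mean is
meaningless — and as a percentage only when predictions are on an original
positive scale.

Per-bin recommendation is two-step: (1) genotypes statistically tied with
the best by a two-sided t-test on the ensemble run distribution
(`SE = sqrt(se_best^2 + se_g^2)`, df = runs - 1, tied iff `p > alpha`,
default `alpha = 0.05`); (2) among the tied, the genotype whose nearest own
trial is closest to the bin wins (ties broken by higher predicted mean,
then id). Minimum distance is the simplest faithful reading of
"geographical representativeness"; genotypes never trialed cannot win.
Note the tie rule's direction: *lowering* `alpha` widens the tied set and
so trades predicted mean for representativeness. Parental maps rank parent
surfaces per bin and suggest the top1 x top2 cross at its additive
mid-parent value — dominance and heterosis are deliberately out of scope.

## Validation

Metrics (Pearson, Spearman with average ranks, RMSE) are computed within
trial and summarized as unweighted mean and SD over trials; pooling records
across trials can reverse within-trial associations (Simpson's paradox), so
pooled correlations are never reported. Schemes: leave-one-trial-out and
leave-region-out (one fold per region label; the overall row pools the
folds' trial-level metrics). By default the marker bank is refit per fold;
a frozen-bank fast mode exists and is flagged, because a bank fitted on all
trials has seen the held-out trial's mean. Per-trial abilities are
interpolated over the grid by ordinary kriging with a spherical variogram
(nugget, partial sill, range) fit by weighted least squares on a 15-lag
empirical semivariogram (weights = pair counts, lags to half the maximum
distance); kriging weights are constrained to sum to one, so with a zero
nugget the surface interpolates the observed abilities exactly.

## What the generator emulates — and what it does not

`simulate_enviromic_study()` produces: spatially autocorrelated covariate
fields (low-rank Gaussian random fields; collinear copies at r ~ 0.9
emulate stacked remote-sensing layers), a founder/hybrid pedigree with a
competitor fraction, genotype intercepts and slopes drawn from
`N(0, Sigma_true (x) A)`, year effects, unbalanced trial placement, and
phenotypes assembled exactly as the reaction-norm model assumes — plus an
explicit environment main-effect term (`env_main_sd` times a standardized
causal-covariate combination). That term is essential: the model's `u` is
zero-mean, so without it expected trial means would carry no environmental
signal and the marker engine would have nothing to learn — real MET data
always has environment main effects. The quality combination is drawn
separately from the slope gradients so it cannot cancel when gradients are
anti-correlated. The true gradients are saturating (`tanh`) functions of
causal covariates — recoverable by trees, not by any single linear
covariate.

The generator does *not* emulate raw imagery, plot-level field structure,
spatial trends within trials, genotype-by-management interaction beyond an
irrigation flag, or non-additive genetics. Passing tests therefore show
correctness of the pipeline's statistics under its own assumptions, not
robustness to the messiness of real trial networks.

Default demo scale (hundreds of bins, 14-40 trials, 24-60 hybrids,
`K_true = 2`, slope variances half the intercept variance, residual SD 0.5)
keeps the full chain in the minutes range; `Sigma_true` defaults produce
rank switching across the gradient, which is the regime the method exists
for. The study-scale defaults (10 000 trees, 1000 runs, 5 km cells) remain
in `reem_config()`.

## Numerical choices and known limitations

* `Sigma` PSD enforcement: eigenvalue floor at `1e-6` of the largest
  eigenvalue ("bending") at every EM iterate and after extrapolation.
* Kinship matrices pass through `psd_repair()`: minimal power-of-ten
  diagonal jitter until Cholesky succeeds; structurally indefinite input is
  an error, not repaired.
* Marker degeneracies: trees with constant predictions over the grid are
  left unclustered and excluded from markers; an all-constant bank is
  allowed (and reported) — every marker is then zero.
* Ties in Spearman metrics use average ranks; zero-variance observed
  vectors yield missing correlations rather than errors.
* The equirectangular projection distorts distances at continental scale;
  the package is intended for regional TPEs (hundreds of km).
* Leave-one-trial-out with per-fold bank refits is honest but expensive;
  the region scheme with a frozen bank is the pragmatic default for
  model comparison at demo scale, and fold counts/tree counts used by any
  script are recorded in its output.
* EM/SQUAREM REML finds the same optimum as plain EM in all oracle tests,
  but like any REML iteration it can be slow on likelihood ridges created
  by nearly collinear markers; such ensemble runs stop at the iteration
  cap and are kept only if the likelihood is flat to 1e-3.
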