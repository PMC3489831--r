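---
title: "Two-scale resource selection: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale resource selection: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundrasel)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The two models

**Landscape scale.** Within a seasonal range, use is contrasted with
availability in a used-available design: each used GPS fix is paired with
one random point drawn uniformly from the seasonal range polygon (the 95%
isopleth of a kernel density estimate of the fixes). The model is a
Bernoulli logit GLMM with crossed random intercepts for animal and year,

$$\operatorname{logit} P(y=1) = \beta_0 + \beta^\top x + a_{animal} + a_{year},$$

estimated by Laplace approximation (`lme4::glmer`). The random intercepts
absorb unequal numbers of fixes per animal and per year; no further
weighting is applied. The "coefficients" of interest are the fixed
effects; their exponentials are relative selection strengths against the
reference vegetation class (sedge-grass meadow, omitted from the dummy
set).

A caveat inherent to the design: the used:available ratio is arbitrary
(1:1 here), so the intercept is not interpretable as a prevalence — it
matters only for the relative-probability map, which is itself a
monotone transform of the linear predictor.

**Patch scale.** Step selection conditions availability on movement: for
each used fix the previous fix is displaced by 5 (rate, bearing) pairs
resampled with replacement from the same animal-season's empirical moves,
and the 1 used + 5 available endpoints form a stratum. The conditional
log-likelihood

$$\ell(\beta) = \sum_s \Big[\beta^\top x_{us} - \log \sum_{j \in s}
\exp(\beta^\top x_{js})\Big]$$

is maximized by Newton-Raphson with step halving until the gradient norm
falls below $10^{-8}$. The stratum conditioning removes the intercept and
any covariate constant within strata, which is why coarse layers
(densities, phenology, precipitation) are excluded from patch-scale
candidate sets: at 100-m step scales they barely vary within a stratum and
carry no conditional information. Rates rather than raw displacements are
resampled so that mixed 2-h and 3-h fix intervals produce correctly scaled
candidate steps, and bearings are resampled as absolute bearings, matching
a movement pool defined by moves between sequential locations.

**Robust standard errors.** Consecutive strata are not independent.
Following the split-sample approach: per-stratum summed deviance residuals
are ordered in time within each animal, centred by an intercept-only
linear mixed model (animal as the grouping factor), and the empirical
autocorrelation function of each animal's series is read off. The lag is
the smallest $L$ with $|ACF(L)| < 1.96/\sqrt{m}$, maximized over animals;
strata are then assigned to two groups in alternating blocks of length
$L$, the model is refitted on each, and the robust covariance is the
average of the two group covariances. With independent data this roughly
$\sqrt{2}$-inflates the naive SE (each group holds half the information),
which is the expected behaviour, and the tests assert it. Coefficients are
declared significant when $\hat\beta \pm 1.96\,SE_{robust}$ excludes zero.

**Validation.** k-fold cross-validation partitions *animals* (not points)
into $k = 5$ folds, avoiding leakage through serial correlation within an
animal. Withheld available points define 10 equal-count score bins
(equal-area in selection score); the Spearman correlation between bin rank
and the area-adjusted frequency of withheld used points is averaged over
folds. The p-value is a one-sided Spearman test on the fold-averaged bin
frequencies — a pragmatic choice, since the construction of the published
statistic is not fully specified; per-fold p-values are also available.

## Covariate engineering

* **Vegetation densities.** For each of the 9 classes, the scale of
  maximum spatial variation is found by three-term local quadrat variance
  (TTLQV): $V_3(b) = \mathrm{mean}\,[(S_1 - 2S_2 + S_3)^2]/(8b)$ over all
  transect positions, averaged over row and column transects (the 2-D
  extension is a design choice; the method is defined for transects). The
  moving-window density at that scale becomes the class's density layer.
  A numerical note: $V_3$ of a two-phase pattern has a broad plateau whose
  maximum sits slightly *below* the patch width (continuously, at about
  15/16 of it — 7.5 for an 8-cell stripe), so the discrete argmax for
  stripes of width 4, 8, 16 is 4, 7, 15. The tests pin the implementation
  to a brute-force oracle rather than to the folklore "peak = patch size".
* **Ruggedness.** Vector ruggedness measure over an 8-cell window: Horn
  finite-difference slope/aspect give each cell a unit surface normal
  $(-g_x, -g_y, 1)/\|\cdot\|$; VRM $= 1 - \|\sum \hat n\|/n$. Edges are
  padded by linear extrapolation so planar terrain is exactly 0 everywhere
  (replication padding would halve edge gradients). The "8-pixel window"
  is read as 8×8; an even window is centred with the extra cell south/east.
* **Phenology.** Green-up is the first 10-day composite with NDVI > 0.1,
  max growth the date of the NDVI maximum (earliest on ties), senescence
  the first date after max growth below 0.1; pixels never exceeding 0.1
  are no-data. NDVI native resolution is coarser than the analysis grid
  and is resampled by nearest neighbour, preserving date semantics.
* **Transforms and standardization.** Elevation and distance to coast are
  log-transformed with a one-cell-size guard, `log(x + cellsize)`, since
  coastal cells have distance 0 (the paper-scale analysis is silent on
  zeros; the guard is the package's choice and is recorded in the design
  table metadata). Ruggedness is square-root transformed. Continuous
  covariates are z-standardized over the *fitting* set (used + available
  combined — the pooled reading of the standardization step); the
  means/sds are stored and reused verbatim for map prediction. Patch
  dummies are left 0/1. Squared terms are added *after* standardization
  when a single-variable logistic comparison improves AIC by more than 2 —
  an operationalization of "detecting non-linearity", logged and
  configurable.
* **Collinearity.** VIF is computed as $1/(1-R^2)$ of each column on the
  others; the single worst column above 3 is dropped and VIFs recomputed,
  iterating to a fixed point. Which density layers survive is data-driven,
  not hard-coded.

## The synthetic-data generator

The generator defines the study conditions for all recovery tests:

* Vegetation is a Gaussian random field (FFT-smoothed white noise,
  autocorrelation length 600 m by default) cut at class quantiles, so
  target proportions are hit almost exactly while classes stay spatially
  clumped. Default proportions are the 9-class scheme of the study
  region's vegetation map (dwarf shrub 43%, tussock tundra 27%, ...,
  moss-lichen 1%).
* The DEM is a smooth field with ~60 m of relief (the coastal plain is
  low-relief) rising gently inland; the sea occupies the northern edge
  (the "coast"), and lakes cover ~8% of the interior — the region is
  lake-rich, and water is no-data for all selection layers.
* NDVI composites every 10 days follow per-pixel Gaussian seasonal curves
  with spatially varying peak date and amplitude, crossing the 0.1
  background in both directions.
* Weather is hourly at two stations: a diurnal temperature cycle plus
  AR(1) noise, and a calm-spell/gamma wind mixture, parameterized so a
  mid-summer month visits all corner regions of the insect index.
* Tracks are correlated random walks with gamma step lengths (mean 400 m
  per 2-h step) and von Mises turning angles, where each step's endpoint
  is chosen among 30 candidates with probability $\propto e^{\beta^\top x}$
  — the exact data-generating process the patch-scale estimator assumes,
  with reflection at the grid edge and water rejected. Step-length and
  turning-angle distributions are conventional movement-ecology defaults,
  not estimates for any particular herd. 2D-fix and PDOP>10 records are
  injected at 1.5% + 1.1% by default, so screening removes ~2.6% of
  records under the default conditions.
* Coefficient-recovery and coverage checks use a direct matched-strata
  simulator (`simulate_clogit_data`) and a random-intercept Bernoulli
  simulator (`simulate_glmm_data`) — the generating processes of the two
  estimators in their pure form.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about field data: GPS fix loss and habitat-biased fix
failure; behavioural states (resting/foraging/relief movement modes) beyond
a single selection rule; attraction to specific geography; insect-driven
movement feedback (weather and movement are generated independently); and
real NDVI cloud artefacts. Recovery results show the estimators are
correct, not that any particular field dataset meets their assumptions.

## Insect activity index

The published index form is not reproduced in the source; the package uses
the minimal function consistent with its quoted corner behaviour — a
separable bilinear ramp, `clamp01((T - T_lo)/(T_hi - T_lo)) *
clamp01((W_hi - W)/W_hi)` with mosquito corners (T_hi 18°C, T_lo 6°C,
W_hi 6 m/s) and fly corners (T_lo 13°C, W_hi 9 m/s) — isolated behind
`insect_params()` so an alternative form can be swapped in. A location is
a high-harassment record when the index exceeds 0.5 (strictly) at either
station in the half-open window 12 h before the fix — half-open so a
record exactly 12 h old is not double-counted between consecutive fixes.
An option lowers the mosquito wind cut-off to 4 m/s, reflecting local
evidence of a lower wind threshold near large lakes.

## Numerical choices and degenerate inputs

* Conditional logistic: Newton with step halving; separation (a diverging
  coefficient) and within-stratum-constant covariates raise errors naming
  the column; strata with entirely constant covariates merely warn (they
  contribute zero information).
* KDE bandwidth is the per-axis normal-reference ("ad hoc") rule
  $h_j = \hat\sigma_j n^{-1/6}$; the isopleth threshold is the smallest
  density whose superlevel set holds ≥95% of mass; level 1 returns the
  full evaluated support rather than trusting a floating-point cumsum to
  reach exactly 1.
* Sedentary filtering: a fix is dropped iff it lies ≤25 m from the last
  *retained* fix; this retains the first fix of every sedentary bout and
  makes the filter idempotent. Seasons use study-area local dates (fixed
  UTC−8 offset, configurable).
* Half-open cell membership `[x0, x0 + cs)` with row 1 at the north edge;
  all distances planar metres (projected CRS; geodesic corrections are
  negligible at study-area scale).
* Availability sampling retries (100×) before dropping a stratum or
  erroring; random landscape points are screened against water by default
  (a flag disables this).

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to
exercise every code path with stable statistics: 100–300² cell grids,
8–20 animals, 350–500 steps per animal, 20 replicate datasets for
bias/coverage/validation summaries. These are the package's reference
conditions for the synthetic study; all are configurable upward.

## Known limitations

* The landscape GLMM covariance is the observed-information (Laplace)
  approximation; no parametric bootstrap is provided.
* The residual-lag procedure reads the ACF per animal and takes the
  maximum — conservative when animals differ strongly in fix frequency.
* Patch-scale surfaces have no intercept and are meaningful only as
  relative rankings (the quantile-classed map is invariant to this).
* No spatially explicit covariance models (GEE, autocorrelated random
  fields) and no Bayesian fitting.
* Raster I/O is plain-text ASCII grid; no GeoTIFF reader is bundled, and
  CRS handling is limited to "a projected system in metres".
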