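---
title: "Decomposing ensemble exposure measurement error: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing ensemble exposure measurement error: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spatiotemporal exposure models built by ensemble learning produce, for
every subject-location-time point, not one prediction but a family of
them — one per ensemble member.  Treating those members as realizations
from a dosimetry system turns the ensemble spread into a direct handle on
the model's measurement error: how large it is, how much of it is shared
across predictions (and therefore does not average out in an
epidemiological regression), and where and when the shared part
concentrates.  `sumaerr` implements that error analysis for air-pollution
exposure ensembles (the motivating case is biweekly NOx predictions in
ppb), but nothing in the machinery is pollutant-specific.

## The error model

For prediction $i$ with reported exposure $Z_i$ (the across-ensemble
mean), each ensemble realization is modelled as

$$X_i = \epsilon_{SM}\,\epsilon_{Mi}\,Z_i + \epsilon_{SA} + \epsilon_{Ai}$$

with four independent error terms: shared multiplicative
$\epsilon_{SM}$ (one draw per replicate, common to all predictions; mean
1, variance $\sigma^2_{SM}$), unshared multiplicative $\epsilon_{Mi}$
(per prediction per replicate; mean 1, variance $\sigma^2_{M}$), shared
additive $\epsilon_{SA}$ (mean 0, variance $\sigma^2_{SA}$, in ppb²),
and unshared additive $\epsilon_{Ai}$ (mean 0, variance $\sigma^2_{A}$).
This is a Berkson-type structure: the realizations scatter around the
reported value, not the other way around.  The shared multiplicative
component is the one that matters most downstream, because error shared
across many predictions inflates the variance of health-effect estimates
without attenuating toward the null in the usual classical-error way.

Two moment identities drive estimation.  Across replicates,

$$\mathrm{Cov}(X_i, X_j) = \sigma^2_{SM} Z_i Z_j + \sigma^2_{SA}
\qquad (i \ne j),$$

$$\mathrm{Var}(X_i) = Z_i^2\left[(\sigma^2_{SM}+1)(\sigma^2_{M}+1)-1\right]
+ \sigma^2_{SA} + \sigma^2_{A}.$$

So an ordinary least squares regression of the pairwise across-ensemble
covariances $C_{ij}$ on the products of means $Z_iZ_j$ identifies
$\sigma^2_{SM}$ (slope) and $\sigma^2_{SA}$ (intercept), and a second
OLS regression of the per-prediction variances $V_i$ on $Z_i^2$
identifies the total relative variance (slope) and the total additive
variance (intercept).  `solve_components()` then solves the system:

* $\hat\sigma^2_{SM} = \max(\text{shared slope}, 0)$,
  $\hat\sigma^2_{SA} = \max(\text{shared intercept}, 0)$;
* $\hat\sigma^2_{M} = (1 + \text{unshared slope}) / (1 + \hat\sigma^2_{SM}) - 1$,
  truncated at 0;
* $\hat\sigma^2_{A} = \text{unshared intercept} - \hat\sigma^2_{SA}$,
  truncated at 0.

Truncation happens *before* the dependent solves (the shared component
is truncated before dividing for the unshared one, the shared additive
before differencing), which matches how practitioners report these
systems: variances cannot be negative, and a negative raw estimate is
read as "no evidence of this component".  The raw untruncated values and
per-component truncation flags are always kept alongside the final
estimates.  When the shared slope is zero the unshared component is
taken to be the unshared slope itself, exactly, rather than through the
division (the two are algebraically identical; the direct path avoids a
spurious last-bit rounding).

Worked check: with a variance-regression slope of 0.0078 and a shared
multiplicative variance of 0.00029, the solver gives
$(1.0078/1.00029) - 1 = 0.00751$ to five decimals — the arithmetic that
`scripts/acceptance.R` re-derives at run time.

### What the regression standard errors mean

Both regressions report nominal `lm()` standard errors and p-values.
For the pairwise regression these are descriptive only: the
$n(n-1)/2$ pair records share the same underlying replicates, so they
are far from independent and the nominal SEs are too small.  The
repeated-subsample spread reported by `run_suma()` (11 independent
draws by default) is the honest robustness measure.

### Numerical choices

* Across-ensemble variances and covariances use the sample ($n_{ens}-1$)
  denominator: replicates are a sample from the dosimetry distribution.
* $Z_i$ is the unweighted across-ensemble mean by default; a replicate
  weight vector is accepted (ensembles are often combined with
  performance weights) and affects $Z$ only, never $V$.
* Self-pairs are excluded from the covariance regression; the diagonal
  information belongs to the variance regression and mixing the two
  would double-count.
* Pairwise statistics are computed blockwise (default 512 rows per
  block) from the row-centered matrix, so a 2500-prediction table
  (~3.1 million pairs) streams through ordinary memory; the result is
  exactly the two-pass covariance, verified against a brute-force double
  loop at 1e-10 relative tolerance.
* The unshared-regression slope cannot be at or below −1 (total relative
  variance would be non-positive); that input is rejected rather than
  truncated.

### Subsampling

Pair computation is quadratic, so the decomposition runs on a seeded
random subset (default 2500 predictions, 11 independent repeats).  All
repeats come from a single random stream initialized from the one
top-level seed, which makes every repeat reproducible from the seed
alone.  Repeats are independent draws; mutually exclusive membership is
not enforced (with 2500 out of millions, overlap is negligible anyway).
`representativeness_report()` compares sample and population
distributions per variable, defaulting to population-quartile bins, so a
sample can be certified representative before its estimates are trusted.

## Labelling high shared error

Each sampled prediction gets a mean covariance — the average $C_{ij}$
over all other predictions in the sample.  Predictions that consistently
covary with the rest carry shared uncertainty.  `dichotomize()` cuts the
distribution at the 80th percentile by default (linear interpolation
between order statistics, `quantile()` type 7, documented for
bit-reproducibility); ties at the threshold are labelled high, so "high"
always means `mean_cov >= threshold`.  On continuous data this labels
exactly the top 20%.

A known artifact, inherited from using unstandardized covariances: the
mean covariance scales with $Z_i$, so predictions with large exposures
tend to rank high regardless of their shared-error content.  The
labelling therefore separates a genuinely high-shared-error subgroup
reliably only when the subgroup's extra shared variance is large
relative to both the background shared variance and the spread of $Z$;
the package's recovery tests use a moderate exposure spread for exactly
this reason, and the limitation should be kept in mind when reading
label-based maps of real data.

Group comparisons between high- and low-labelled predictions use the
standard parametric Welch two-sided t-test (unequal variances), with the
confidence interval reported on the low-minus-high difference.
Season tabulations derive meteorological seasons from dates
(December–February winter, and so on), and per-category tests compare
each category's high/low split against the first category by two-sample
proportion test.

## The spatial model

The odds that a prediction is labelled high are modelled as

$$\mathrm{logit}\, p(x, y) = s(x, y) + \gamma' \mathbf{w}$$

with a bivariate smooth of projected planar location (meters; geographic
coordinates are not accepted) and optional parametric covariate terms.
The smooth is a penalized thin-plate regression spline fitted by
`mgcv::gam()` with REML smoothness selection.  A local-scoring fit with
a bivariate loess smoother is the other classical implementation of this
model; the penalized-spline route was chosen because it is the
established, actively maintained GAM machinery in R, selects its own
smoothness, and its approximate inference for smooths is well studied.

Two tests of the spatial term are reported and they behave differently:

* `s_p_value`, the Wald-type approximate p-value of the smooth from the
  `mgcv` summary — well calibrated under the null (roughly uniform in
  simulation) but conservative, i.e. weak against compact hotspots;
* `lrt_p_value`, the deviance comparison of the fitted model against the
  same model with the smooth removed — the natural "is there spatial
  variability at all" test, decisively powered, but slightly liberal at
  loose thresholds because the smooth's effective degrees of freedom are
  estimated.  Use it at stringent thresholds (0.001 or below), where
  simulation shows no null inflation.

### The odds-ratio surface

`predict_surface()` evaluates the model on an evenly spaced grid
(default 50 × 50 over the bounding box) clipped to the convex hull of
the observed locations — the model should not extrapolate outside where
predictions exist.  Covariates, if present, are held at their sample
median (numeric) or modal level (categorical), so the surface isolates
the spatial term.  Each point's odds ratio is taken relative to the
sample-average predicted log-odds; that baseline choice is arbitrary but
must be fixed, and it changes the printed OR range, so it is stated here
prominently.  Because thin-plate smooths depend on coordinates only
through distances, the surface is invariant to translating the
coordinate system.

A grid point is flagged hot (cold) when its pointwise $(1-\alpha)$
z-interval on the link scale lies entirely above (below) the baseline.
The default $\alpha = 5\times10^{-7}$ is in the spirit of a false
discovery rate correction over the thousands of grid points examined;
the exact family size such a correction assumes is not reconstructable,
so $\alpha$ is exposed as a plain parameter, and users who prefer a
data-driven band can apply `p.adjust()`-style corrections to the grid's
pointwise p-values themselves.  At this default, null simulations flag
essentially nothing (well under one grid point per run on a 50 × 50
grid).

### Iterative covariate selection

`select_covariates()` mirrors the map-then-explain workflow: starting
from the location-only model, candidates are added one at a time, and a
candidate is retained automatically when it moves the surface's OR
range — the width or either endpoint — by at least 10% relative to the
model without it.  "Did the spatial pattern change" is inherently a
judgment call on maps; the function quantifies it as the Jaccard overlap
of flagged areas before and after, and reports it for human review
rather than deciding on it.  Retained candidates accumulate, so each
later candidate is judged against the model containing all earlier
keepers; the procedure is order-dependent by construction, as any
one-at-a-time forward selection is.

Covariate effects from the final model are reported per
interquartile-range increase for continuous terms
($\mathrm{OR} = e^{\beta \cdot IQR}$, Wald 95% intervals) and per level
against the reference for categorical terms.

## The synthetic-data generator

`simulate_ensembles()` draws directly from the generative model:
multiplicative errors are lognormal re-parameterized to mean exactly 1
and the target variance (keeping factors positive), additive errors
normal.  Only the first two moments are pinned down by the model, and
the estimators depend only on those moments, so the lognormal choice is
a convenience, not an assumption.  Shared terms are drawn once per
replicate per sharing unit — the structure under which the two moment
identities hold exactly.  Sharing units can be refined by period
(per-period multipliers of the shared variance; different periods then
share nothing, which is what a time-stratified analysis assumes) and by
group or spatial disc (members carry an extra shared factor multiplied
onto the global one, so within-group covariance exceeds cross-group
covariance while everything still covaries through the background term).

Negative simulated exposures are possible with additive noise and are
retained by default so the moment identities stay exact; a truncation
switch exists for realism experiments, at the cost of biasing the
estimators slightly.

`simulate_study()` assembles a study-shaped fixture: lognormal exposures
with median near 30 ppb spanning roughly 2–280 ppb; three calendar-year
period tertiles with shares 0.33/0.31/0.36 and per-period shared
variances 0.00036/0.00015/0.00015 (earliest largest); unshared
multiplicative variance 0.0075; no additive error; one compact region
holding about 6% of predictions with extra shared variance 0.0018
(total near 0.002); and traffic density, population density and
dispersion-model non-freeway NOx elevated inside that region.  These
defaults are the regime the estimators are designed for and are not
meant to be tuned per run.

What the generator does *not* emulate — and what passing recovery tests
therefore do not certify about real data: spatially smooth exposure
fields ($Z$ is independent of location), spatial autocorrelation in the
covariates beyond the single high-error region, sharing that decays with
distance or persists within a location over time ("within-shared"
error), replicate weights, and any dependence of error magnitude on the
exposure model's own covariate inputs.

## Problem sizes and test design

The package's simulation-based checks run at deliberately modest sizes
chosen to make the properties sharp without waste: oracle equivalence on
tables up to 200 × 20 over 10 seeds; parameter recovery at
1000 predictions × 120 replicates over 20 seeds (mean recovered
multiplicative components within 25% of truth); stratified-ordering
recovery at 400 predictions per period; spatial null calibration and
3×-hotspot power at n = 2500 over 20 seeds each.  The truncation
behaviour of the additive components in the recovery regime deserves a
note: with true additive variances of zero, the raw intercept estimates
straddle zero almost symmetrically, so whether a given run truncates
them is close to a coin flip — the tests assert the documented behaviour
and flags, and treat "how often" as the near-50% event it is.

## Known limitations

* Pairwise-regression SEs are nominal under dependence (see above).
* The mean-covariance label inherits the exposure-magnitude artifact.
* $\alpha$ for surface flagging is a constant, not a fitted FDR level.
* The OR surface baseline (sample-average log-odds) is a convention;
  ranges are comparable only across models using the same baseline.
* Forward covariate selection is order-dependent and the
  "pattern-change" criterion is reported, not auto-decided.
* No correction of downstream health-effect estimates is attempted;
  the decomposition quantifies error, it does not yet propagate it.
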