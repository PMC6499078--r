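# sumaerr

Quantify the measurement error hiding inside ensemble-based exposure
prediction models — and map where the dangerous, *shared* part of it
lives.

Ensemble-learning exposure models (the motivating case: biweekly
residential NOx predictions in ppb from a 120-member ensemble) provide
many realizations of each prediction, not just one.  Treating those
replicates as draws from a dosimetry system, `sumaerr` decomposes the
implied exposure measurement error into four variance components —
**S**hared and **U**nshared, **M**ultiplicative and **A**dditive — and
then identifies and explains the spatial and temporal concentration of
shared multiplicative measurement error (SMME), the component that
inflates uncertainty in downstream epidemiological regressions without
averaging out.  The intended users are exposure modellers and
environmental epidemiologists who have an ensemble and want to know how
much of its spread is shared, where, and why.

## The model

Each realization of prediction *i* (reported exposure *Z*ᵢ, the
across-ensemble mean) is modelled as

    X_i = e_SM * e_Mi * Z_i + e_SA + e_Ai

where `e_SM`, `e_Mi` are shared/unshared multiplicative errors (mean 1,
variances σ²_SM, σ²_M) and `e_SA`, `e_Ai` shared/unshared additive
errors (mean 0, variances σ²_SA, σ²_A).  Across replicates this implies

    Cov(X_i, X_j) = σ²_SM · Z_i Z_j + σ²_SA          (i ≠ j)
    Var(X_i)      = Z_i² [(σ²_SM+1)(σ²_M+1) − 1] + σ²_SA + σ²_A

so OLS of the pairwise covariances C_ij on the products Z_i·Z_j gives
σ²_SM (slope) and σ²_SA (intercept), OLS of the variances V_i on Z_i²
gives the total relative variance and total additive variance, and
`solve_components()` solves for all four (truncating negative raw
estimates to zero, truncation flags kept).  Predictions in the top 20%
of mean pairwise covariance are labelled high-SMME, and a logistic GAM,
`logit p(x, y) = s(x, y) + γ'w`, maps the odds of a high label over
space and screens covariates that explain the pattern.

## Worked example

Everything below runs on a synthetic study generated by the package (no
external data needed): three calendar-period tertiles with the earliest
carrying ~2.4× the shared error of the later ones, plus one compact
"high-error city" region (~6% of predictions) with extra shared
variance.

```r
library(sumaerr)

study <- simulate_study(n_pred = 1200, n_ens = 120, seed = 42)

# per-period decomposition (each period independently subsampled)
stratified_suma(study$table, study$meta, "period",
                sample_spec(400, 1, seed = 42))
#> Stratified SUMA decomposition by 'period'
#>     stratum sigma_SM2 sigma_M2   n
#> 1 2001-2004 0.0001470 0.006579 380
#> 2 2005-2012 0.0001673 0.007803 400
#> 3 1992-2000 0.0005290 0.008508 397
```

The earliest period's shared multiplicative variance (0.00053) stands
well above the later periods' (~0.00015), recovering the generative
ordering; the unshared component (~0.0075) dwarfs the shared one, which
is the typical regime — unshared error is visible in every prediction's
spread, shared error only in how predictions co-move.

```r
# label high-SMME predictions and see where they sit
pr     <- pairwise_stats(study$table)
labels <- dichotomize(mean_covariances(pr))
labels
#> SMME labels: 240 high / 960 low (cut at the 80th percentile, threshold 0.1895 ppb^2)

tabulate_labels(labels, study$meta, "region")
#>          category n_low   pct_low n_high pct_high      p_value
#> 1       elsewhere   926 96.458333    196 81.66667           NA
#> 2 high_error_city    34  3.541667     44 18.33333 3.147495e-16
```

The planted region holds under 4% of the low-SMME predictions but over
18% of the high ones — the enrichment signature that flags a location
whose predictions carry shared uncertainty.

```r
# map the odds of high SMME and screen covariates
gam     <- fit_smme_gam(labels, study$meta,
                        c("traffic_density", "population_density"))
surface <- predict_surface(gam, grid_n = 40)   # OR per grid point,
                                               # hot/cold flags at alpha = 5e-7
covariate_odds_ratios(gam)                     # per-IQR odds ratios, Wald CIs
```

`run_full_pipeline()` chains all of the above (decomposition with
repeated subsamples, labelling, comparisons, GAM, surface, OR table)
from a YAML or list config and writes a CSV/GeoJSON/JSON report bundle;
`inst/cli/suma.R` exposes the same steps as shell subcommands
(`simulate`, `sample`, `decompose`, `label`, `compare`, `map`,
`run-all`).

See the vignette (`vignettes/suma-error-decomposition.Rmd`) for the
estimators' assumptions, numerical conventions, and the design of the
synthetic-data generator.

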