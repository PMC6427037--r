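# coralbleach

Tools for analysing global coral-bleaching survey compilations against
weekly sea-surface temperature (SST) records. The package is aimed at
reef ecologists and biostatisticians working with standardized
bleaching surveys (percent of colonies bleached per site visit) and
gridded SST products: it computes the thermal-stress covariates the
field uses, fits a hierarchical Bayesian model of bleaching intensity,
checks that model against the data's zero inflation, and tests whether
the temperatures at which bleaching begins have shifted between
decades.

## The model

Percent bleaching at survey *i* is modelled as a negative-binomial
count with a log link (zero-inflated, overdispersed data):

    o_i ~ NB(p_i, k),   E(o_i) = p_i,   Var(o_i) = p_i + p_i^2 / k
    log(p_i) = b0 + sum_j gamma_j * z_ij + a_s(i)

with standardized covariates `z` (SST at survey, SST anomaly and
thermal-stress-anomaly statistics and >= 1 °C exceedance frequencies,
Degree Heating Weeks, the long-run SST warming rate, climatological
SST, latitude, depth, year, ecoregion species diversity) and nested
random effects: site effects `a_s ~ N(R_r, tau)` within ecoregion
effects `R_r ~ N(mu + b_div * d_r, T)`, where `d_r` is standardized
ecoregion diversity. The posterior is sampled with JAGS (via `rjags`);
effects are classified positive / negative / null by whether their 95%
credible interval excludes zero.

Around the model sit:

* `compute_climatology()`, `compute_anomalies()`, `compute_dhw()`,
  `compute_rate_of_change()`, `metrics_for_survey()` — CoRTAD-style
  weekly thermal metrics (52-week climatology, MMM, SSTA/TSA, DHW over
  a trailing 12-week window with the >= 1 °C hotspot rule);
* `build_analysis_table()` — missing-data removal, greedy collinearity
  pruning at |r| > 0.65, standardization (all drops recorded);
* `posterior_predictive_check()` — split checks for zero-inflated
  counts: a Bayesian P-value on the mean of non-zero values, plus a
  zero-pattern comparison;
* `fit_weibull_mle()`, `lrt_decades()`, `bleaching_onset_ssts()` — the
  decadal shift analysis: two-parameter Weibull fits to the SSTs at
  which bleaching was recorded, compared across decades by a
  likelihood-ratio test (chi-squared, 2 df);
* `ecoregion_zscores()`, `latitude_profile()`, `effort_correlation()`,
  `annual_trend()` — descriptive spatial and temporal layers;
* `sim_config()`, `gen_world()`, `gen_bleaching()` — a synthetic-data
  generator (gridded SST with seasonality, warming and heatwave blocks;
  ecoregions with an equatorial diversity gradient; surveys drawn from
  the model itself) so the whole chain is testable offline.

The `analysis/` directory holds numbered scripts (`01_simulate.R` …
`07_summaries.R`) that run the full chain on the default synthetic
study and write their tables under `results/`; `vignettes/` documents
the methods and design decisions.

## Worked example

```r
library(coralbleach)

# a small synthetic study: 8 ecoregions x 10 sites, 20 years of weekly SST
cfg <- sim_config(n_ecoregions = 8, sites_per_ecoregion = 10,
                  weeks = 1040, start_year = 1998, seed = 7)
world <- gen_world(cfg)
surveys <- gen_bleaching(world, cfg)

covs <- covariate_table(world, surveys[c("site_id", "date")])
covs$bleaching_pct <- surveys$bleaching_pct
tab <- build_analysis_table(covs, world$diversity, prune_threshold = 0.65)
fit <- fit_bleaching_model(tab, model_spec(n_chains = 2, n_adapt = 300,
                                           n_burnin = 500,
                                           n_iterations = 800, seed = 1))
eff <- summarize_effects(fit)
```

which prints (surveys: 221, zero fraction 0.44; 8 of 18 candidate
covariates dropped by the 0.65 pruning rule):

```
            covariate   mean    l95    u95 classification
2             sst_min  0.229 -0.371  0.713           null
...
7      tsa_freq_stdev -0.425 -0.758 -0.058       negative
9  rate_of_sst_change  0.277  0.060  0.521       positive
11               year  0.587  0.316  0.848       positive
```

At this deliberately small size only the strongest signals clear the
95% credible-interval rule, and they surface partly through correlated
proxies of the generative covariates (the pruning step keeps one
member of each collinear family). The fit warns that `b0` and `mu`
have not converged: those two parameters are identified only through
their sum (see the methods vignette) and are never interpreted
individually. The decadal analysis on the same table,

```r
onset1 <- bleaching_onset_ssts(tab$data, c(1998, 2006))
onset2 <- bleaching_onset_ssts(tab$data, c(2007, 2017))
lrt_decades(onset1, onset2)
```

prints onset-SST means of 28.44 °C vs 28.50 °C and

```
<lrt_result> chi2 = 0.153 on 2 df, Pr(>chi2) = 0.9265
```

— no detectable decade shift, as expected for a generator whose only
between-decade change is a 0.02 °C/yr background trend at this sample
size. Calibration experiments at larger sizes (coefficient coverage,
LRT size and power, posterior-predictive calibration) live in the test
suite.

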