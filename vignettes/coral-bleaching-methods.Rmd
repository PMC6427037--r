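---
title: "Modelling global coral bleaching against thermal stress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global coral bleaching against thermal stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coralbleach` implements a complete analysis chain for global
coral-bleaching survey compilations: thermal-stress covariates from
weekly sea-surface temperature (SST), a hierarchical Bayesian
negative-binomial model of percent bleaching, posterior-predictive
diagnostics for zero-inflated counts, a decadal Weibull/likelihood-ratio
analysis of bleaching-onset temperatures, and descriptive
spatial/temporal summaries. This vignette explains the model, the
conventions and defaults, what the synthetic-data generator does and
does not emulate, and the design decisions that were genuinely open.

## The observation model

Percent bleaching at a survey is an integer in 0–100 (the percent of
surveyed colonies recorded as bleached). The data are strongly
zero-inflated — roughly half of reef surveys record no bleaching — and
overdispersed, so the model treats the outcome as a negative-binomial
count with a log link:

$$o_i \sim \mathrm{NB}(p_i,\,k), \qquad
  \mathrm{E}(o_i) = p_i, \qquad
  \mathrm{Var}(o_i) = p_i + p_i^2/k,$$

$$\log p_i = b_0 + \sum_j \gamma_j z_{ij} + a_{s(i)},$$

where $z_{ij}$ are standardized covariates and $a_s$ is a site-level
random effect. Sites are nested in ecoregions, which carry the species
diversity covariate $d_r$:

$$a_s \sim N(R_{r(s)}, \tau), \qquad
  R_r \sim N(g_r, T), \qquad
  g_r = \mu + b_{\mathrm{div}}\, d_r.$$

Conventions adopted here:

* $\tau$ and $T$ are **standard deviations** in every public interface
  (samplers that parameterize by precision convert internally); "site
  variance" vs "site sd" is a classic source of silent errors, so one
  unambiguous unit is exposed.
* the negative binomial is in **mean–dispersion form** (`mu`/`size` in
  R's `rnbinom`), so the variance identity above holds exactly;
* **diversity is standardized** like every other covariate, so
  $b_{\mathrm{div}}$ is directly comparable to the $\gamma_j$;
* observed percentages are modelled without truncation at 100. The
  generator caps raw counts at 100 and reports the cap rate; under the
  default configuration it is below 0.1%, so the missing truncation
  correction is negligible.

### Priors and sampling

Coefficients ($b_0$, $\gamma$, $\mu$, $b_{\mathrm{div}}$) get vague
Normal(0, sd 100) priors; the dispersion $k$ a Gamma(0.01, 0.01); the
random-effect sds half-Cauchy(0, 2.5). All are configurable through
`model_spec()`. The posterior is sampled with JAGS (via `rjags`);
chains are initialised at neutral values with per-chain Wichmann–Hill
seeds, so a fit is exactly reproducible from its spec. The default
spec runs 3 chains with a 4000-iteration burn-in and 5000 retained
iterations; tests and the worked examples shorten the chains because
the identified parameters reach usable effective sizes quickly at
desk-scale problem sizes (hundreds to ~1000 surveys).

**A deliberate non-identifiability.** $b_0$ and $\mu$ enter the
likelihood only through their sum ($\log p_i$ contains $b_0 + a_s$, and
the $a_s$ are anchored at $\mu + b_{\mathrm{div}} d_r$). With vague
priors the posterior has a flat ridge along $b_0 + \mu = \text{const}$:
each parameter's chain wanders while the sum, the $\gamma_j$,
$b_{\mathrm{div}}$, $k$, $\tau$ and $T$ mix well. The model is kept in
this form because it is the form the field uses; the consequence is
that `convergence_check()` (split R-hat, threshold 1.1) flags `b0` and
`mu` on essentially every fit. That warning is informative, not
spurious — inference should be read from the identified parameters, and
the effect classification never involves $b_0$ or $\mu$ individually.

### Effect classification

`summarize_effects()` reports posterior means with 50% and 95%
equal-tailed credible intervals and classifies each effect `positive`
(95% CrI entirely above 0), `negative` (entirely below), or `null`
(crosses 0) — the usual forest-plot rule for these models.

## Thermal-stress covariates

All metrics derive from one weekly SST series per site (nearest grid
cell center; no interpolation — at the ~4 km to 1° resolutions involved,
within-cell gradients are far below the noise of the bleaching
response):

* **Climatology**: long-term mean per week-of-year. The calendar is
  folded to exactly 52 weeks (week 53 merged into 52) so indexing is
  fixed-width. The **MMM** (maximum monthly mean) is the warmest of
  the twelve long-term calendar-month means.
* **SSTA** = SST − weekly climatology; **TSA** = SST − MMM. Frequency
  metrics count weeks with an anomaly ≥ 1 °C; dispersion metrics are
  standard deviations of the weekly anomalies and of the per-year
  exceedance counts.
* **DHW** follows the NOAA Coral Reef Watch convention: the sum of
  (SST − MMM) over the trailing 12-week window, counting only weeks at
  least 1 °C above MMM, in °C-weeks. The defining phrase "1 °C above
  the warmest-month climatology" underdetermines the window and
  threshold; the CRW convention is the standard resolution and both are
  exposed as arguments.
* **Rate of SST change**: OLS slope of weekly SST on fractional years.
* All "history" metrics (min/max/sd, frequencies, rate) use the series
  **up to the survey date**, not the full record — a survey cannot see
  its future.

Missing weeks beyond a configurable gap fraction (default 10%) flag the
survey rather than silently imputing; flagged records are dropped by
`drop_incomplete()` with a recorded reason, mirroring the usual
"remove sites with missing environmental data" rule.

## Preprocessing

`build_analysis_table()` applies, in order: missing-data removal (with
per-row reasons and the overall dropped fraction), collinearity pruning,
and standardization to mean 0 / sd 1 with the sample (n−1) standard
deviation. Pruning is greedy: while any pair of covariates has
|Pearson r| above the threshold (default 0.65), drop the member of the
worst pair with the larger mean absolute correlation to everything
else, ties broken by column order. The procedure is deterministic given
column order and every drop is recorded with its trigger pair, so the
retained set is auditable; a permuted input can legitimately retain a
different (equally sized) set, which is why the audit trail matters.
Constant columns are excluded before correlation (undefined r) with a
warning. Standardization parameters are stored so a fitted coefficient
can be mapped back to natural units (`unstandardize_coef()`).

## Posterior-predictive checks

A plain mean-based Bayesian P-value is useless for a zero-inflated
outcome (the zeros dominate any mean discrepancy), so the check is
split:

* `ppc_nonzero()`: for each posterior draw, simulate a full replicate
  dataset and compare its mean over non-zero values with the observed
  mean over non-zero values; the P-value is the fraction of replicates
  exceeding the observed.
* `ppc_zero()`: at observed-zero positions, the fraction of replicate
  values equal to zero (zero-match rate), plus the mean and sd of
  replicate bleaching there when the replicate overestimates.

Replicates condition on each draw's site effects ("mixed" predictive),
which is what a JAGS monitor of replicated data inside the model would
produce; refreshing the effects from their priors would test a
different (marginal) question. Replicates whose values are all zero
contribute a non-zero mean of 0 by convention. All PPC output is
bit-reproducible given the replicate seed.

## Decadal shift in bleaching-onset SSTs

"Onset" is operationalized as any survey with bleaching > 0%; no
threshold is imposed because none is standard. Survey-week SSTs of
onset surveys are grouped into two decades (defaults 1998–2006 and
2007–2017) and each group is fitted with a **two-parameter Weibull**
(no location shift — consistent with the magnitude of reported
shape/scale values for such data). The MLE solves the profile equation
for the shape by bracketed root-finding (the profile is strictly
increasing, so the root is unique; samples are rescaled by their
maximum to keep $x^c$ finite at large shapes) and recovers the scale in
closed form. The decades are compared by a likelihood-ratio test of
pooled vs separate fits on 2 degrees of freedom (shape and scale both
free per group). Type-I calibration and power of this test are verified
by simulation in the test suite.

## The synthetic world

`sim_config()` + `gen_world()` + `gen_bleaching()` build a fully
synthetic study so every stage is testable without downloads:

* **SST grid**: 1° cells spanning 30°S–30°N, weekly from 1982 (1872
  weeks ≈ 36 years by default). Each cell = equator-peaked baseline
  (29.5 °C falling quadratically to 26 °C at 30°) + 3 °C seasonal
  sinusoid (phase flipped 26 weeks across the Equator) + 0.02 °C/yr
  warming + white noise (sd 0.3 °C) + sparse positive anomaly blocks
  (0.5 events/cell/yr, magnitude ~1.5 °C, a few weeks long) standing in
  for marine heatwaves. An optional yearly ramp in the event rate
  emulates intensifying thermal stress.
* **Ecoregions and sites**: contiguous latitudinal bands; species
  richness decays from ~600 at the Equator to ~150 at the band edges
  (the equatorial diversity gradient); sites uniform within their band,
  depths 2–12 m (shallow reef survey range).
* **Effort**: per-site revisit counts follow a negative binomial
  matched to a mean of 2.75 surveys and sd 3.17 (the right-skewed
  revisit pattern of global volunteer-survey programs), zeros promoted
  to one visit; surveys fall in the final two decades.
* **Bleaching**: drawn exactly from the hierarchical model above, with
  defaults $b_0 = 0.5$, $\gamma = (0.6\,[\mathrm{SSTA\ freq}],
  -0.5\,[\mathrm{SSTA\ sd}], 0.15\,[\mathrm{DHW}],
  0.2\,[\mathrm{SST\ trend}], 0\,[\mathrm{depth}])$,
  $k = 0.6$, $\tau = 0.3$, $T = 0.25$, $b_{\mathrm{div}} = -0.2$,
  $\mu = 0$ — signs chosen to reproduce the qualitative structure of
  the field results (bleaching rises with the frequency and intensity
  of thermal-stress anomalies, falls with anomaly variability and
  diversity) at magnitudes that leave the outcome roughly half zeros.
  The strongest generative effects sit on covariates whose
  standardized distributions have moderate tails (anomaly frequency
  and dispersion): DHW at survey dates is zero-inflated with extreme
  positive z-scores, and a large coefficient on it under the log link
  produces occasional astronomically large negative-binomial means
  whose draws would be capped at 100 far more often than the 0.1%
  cap-rate budget allows — the cap would then act as an unmodelled
  truncation visible in the posterior-predictive checks. The latent
  effects, design matrix and standardization constants are attached to
  the result for recovery experiments.

What the generator does **not** emulate: land/ocean masks and real
coastline geometry, cloud-masked missing-data patterns, spatial
autocorrelation of anomalies across cells, observer error in bleaching
estimates, and the real spatial clustering of survey effort. Passing
recovery and calibration tests on this world therefore demonstrates
that the estimation machinery is correct under the model's own
assumptions — not that the model is adequate for any particular real
dataset; that question is exactly what the posterior-predictive checks
are for.

## Numerical choices and degenerate inputs

* Weibull MLE: root bracketed in shape ∈ [10⁻³, 10⁵], `uniroot`
  tolerance 10⁻¹², gradient verified < 10⁻⁸; non-positive samples and
  n < 10 are rejected.
* LRT statistic clamped at 0 (the separate fit can lose to the pooled
  fit only by rounding).
* Split R-hat on half-chains; constant chains return NA with a
  `degenerate` flag instead of dividing by zero.
* Wilson score intervals for annual bleaching probabilities (better
  small-n behaviour than Wald; the interval bounds respect [0, 1]).
* Spearman effort check uses the tie-corrected approximation
  (`exact = FALSE`); constant prevalence across bands returns a flagged
  NA rather than an arbitrary rho.
* Ecoregion z-scores with identical means return 0 rather than 0/0.
* Week 53 folding, the ≥ 1 °C anomaly thresholds, the 12-week DHW
  window, the 0.65 pruning threshold, the 10% missing-gap tolerance,
  5° latitude bands and the 10-survey ecoregion rule are all defaults,
  not constants.

## Problem sizes

The worked analysis scripts (`analysis/01…07`) and the test suite run
on the default synthetic world (300–360 sites, ~1000 surveys, 36 years
of weekly SST) with shortened MCMC (2–3 chains, a few hundred to ~1500
retained iterations), chosen so each script is a minutes-scale run on
one CPU. Calibration experiments use 20 replicate datasets at that
size. The model-spec defaults remain the full 3 × (4000 + 5000)
configuration for real analyses.

## Known limitations

* The b₀/μ ridge (above) is inherent to the model as specified.
* The negative binomial ignores the 100% ceiling; for datasets where
  high bleaching percentages are common a truncated or beta-binomial
  observation model would be more appropriate.
* Pruning at a fixed correlation threshold is order-sensitive in the
  membership (not the size) of the retained set.
* One site maps to one grid cell; surveys on reefs straddling cell
  boundaries inherit whichever cell center is nearest.
* The effort check is computed at the latitude-band level by default;
  other aggregation units (ecoregion) are supported but the choice of
  unit changes the question being asked.
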