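---
title: "Methods: EHF heatwave detection and the space-time-stratified case-crossover model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHF heatwave detection and the space-time-stratified case-crossover model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwavecc)
```

## Overview

`heatwavecc` implements an end-to-end analysis of the short-term association
between heatwave exposure and daily emergency department (ED) presentation
counts:

1. gridded sub-daily climate fields are aggregated to daily regional series;
2. heatwave days are detected with the Excess Heat Factor (EHF) and graded
   into severity tiers, under two index variants (temperature only, and
   temperature plus humidity via a heat index);
3. ED line-list records are grouped by ICD-10 chapter ranges and aggregated
   to region-day counts;
4. the exposure–outcome association is estimated with a
   space-time-stratified case-crossover design, fitted by a hand-written
   conditional quasi-Poisson maximum-likelihood routine;
5. descriptive and trend summaries reproduce standard published-table
   arithmetic; and
6. a synthetic data generator supports calibration and power studies with
   known truth.

## The Excess Heat Factor

For a daily driver series $x_i$ (daily mean temperature for variant T, or a
heat index of daily mean temperature and relative humidity for variant TH),
the index for day $i$ compares the significance-window mean — by default the
three days starting at $i$ —

$$\mathrm{EHI}_{sig}(i) = \tfrac{1}{3}\left(x_i + x_{i+1} + x_{i+2}\right) - T_{95}$$

with a climatological threshold $T_{95}$ (the 95th percentile of the driver
over a fixed reference period), and with the mean of the preceding 30 days

$$\mathrm{EHI}_{accl}(i) = \tfrac{1}{3}\left(x_i + x_{i+1} + x_{i+2}\right) -
\tfrac{1}{30}\sum_{j=i-30}^{i-1} x_j.$$

The Excess Heat Factor is their product with the acclimatisation term floored
at one:

$$\mathrm{EHF}(i) = \mathrm{EHI}_{sig}(i) \times \max\{1, \mathrm{EHI}_{accl}(i)\}
\quad [^\circ C^2].$$

A day is a heatwave day iff $\mathrm{EHF} > 0$: the three-day mean embeds the
persistence requirement, so no separate run-length rule is applied.
Severity is graded against the 85th percentile $\mathrm{EHF}_{85}$ of the
strictly positive reference-period EHF values: *severe* when
$\mathrm{EHF} \ge \mathrm{EHF}_{85}$ and *extreme* when
$\mathrm{EHF} \ge 3\,\mathrm{EHF}_{85}$ (closed thresholds). Because severe
and extreme days are individually rare, the analysis exposure collapses them
into one `severe_extreme` level, giving the three-level exposure
`none < low < severe_extreme`.

All knobs live in `ehf_params()`: the reference period (default 1960–2011),
the two percentiles (95/85), window lengths (3/30), the extreme multiplier
(3), the significance-window orientation (`"forward"`, the default, labels
day $i$ from days $i..i+2$; `"trailing"` from $i-2..i$), and the labelling
rule (`"point"`, the default, labels day $i$ by $\mathrm{EHF}(i)$ alone;
`"paint"` additionally propagates a window's label to every day it covers).
Days whose windows are incomplete (the first 30 and, in forward orientation,
the last 2 of a series) have undefined EHF and are never heatwave days.

### Heat index and humidity

Variant TH replaces the driver with the US National Weather Service heat
index (`compute_heat_index()`): below 80 °F it uses the simple Steadman-type
average, at or above 80 °F the Rothfusz regression with the standard low-RH
(RH < 13 %, 80–112 °F) and high-RH (RH > 85 %, 80–87 °F) adjustments.
Internally the computation is in °F; inputs and outputs are °C. Relative
humidity can be derived from dewpoint with the Magnus formula
(`derive_relative_humidity()`); supersaturated inputs (dewpoint above
temperature) are clamped to 100 % and logged rather than rejected.

## The case-crossover model

Counts are analysed at the region-day level. Each region-day belongs to a
stratum defined by region × year × month × day-of-week, so every day is
compared only with days of the same weekday in the same calendar month —
this removes seasonality, long-term trends, and weekly patterns by design,
and any covariate constant within a stratum is uncontaminated and
inestimable.

Conditioning a Poisson model on the observed stratum totals $N_s$ gives the
product-multinomial conditional likelihood

$$\ell(\beta) = \sum_i y_i x_i^\top \beta -
\sum_s N_s \log \sum_{i \in s} \exp(x_i^\top \beta),$$

which is free of the stratum intercepts. `ccfit()` maximises it by
Newton–Raphson from $\beta = 0$ with step-halving, so the fit is completely
deterministic. Fitted means are $\mu_i = N_s w_i / W_s$ with
$w_i = \exp(x_i^\top\beta)$; the observed information is

$$I(\beta) = \sum_i \mu_i x_i x_i^\top -
\sum_s \tfrac{1}{N_s}\Big(\sum_{i\in s}\mu_i x_i\Big)
\Big(\sum_{i\in s}\mu_i x_i\Big)^\top ,$$

computed as `crossprod(X * sqrt(mu)) - crossprod(Sx / sqrt(Ns))` for
stability and speed.

Overdispersion is handled quasi-likelihood style: the Pearson dispersion

$$\hat\varphi = \frac{1}{n - p - K} \sum_i \frac{(y_i - \hat\mu_i)^2}{\hat\mu_i}$$

divides by residual degrees of freedom that subtract both the $p$ regression
parameters and the $K$ conditioned-out strata, and scales the inverse
information to give the covariance. No floor is applied to $\hat\varphi$;
underdispersed data legitimately shrink the intervals. Wald intervals use
`qnorm(0.975)` (not the rounded 1.96) so that `confint()` is exactly
consistent with the reported standard errors.

Before fitting, `build_strata()` drops (and counts) rows with missing
covariates, strata with zero total count, and strata in which every
covariate is constant — none of these contribute to the conditional
likelihood. Separation (a covariate that perfectly predicts where the counts
fall within strata, so the MLE is infinite) is detected when any
$|\hat\beta_j| > 15$ — a rate ratio above $3\times10^6$, which no real
region-day design produces — and reported as an error naming the column,
whether it occurs mid-iteration or at a spuriously "converged" point where
the score is flat.

`ccfit()` returns a classed S3 object with the usual `print`, `summary`,
`coef`, `vcov`, `confint`, `fitted`, `residuals` and `nobs` methods, and
`rate_ratios()` formats exponentiated effects with the reporting convention
(RR to 3 decimals; percentage change half-up to 1 decimal).

### Oracles

The fitter is verified two ways, both in the test suite: (i) on a single
stratum with a binary exposure the conditional MLE has the closed form
$\widehat{RR} = \bar y_{exposed}/\bar y_{unexposed}$; (ii) on random small
instances the conditional estimates must equal the covariate coefficients of
an unconditional Poisson GLM with one dummy intercept per stratum
(a classical equivalence), fitted by `stats::glm` at tight tolerance.

## Reporting helpers

`crosstab_indexes()` / `crosstab_from_cells()` compute the agreement table
between the two index variants and the discordance percentages from either
calendars or printed cells. `heatwave_trend()` counts annual heatwave
location-days and fits a Gamma GLM with log link via `fit_annual_trend()`;
zero-count years lie outside the Gamma support and are excluded (and
reported), not imputed. `descriptive_table()` and `period_comparison()`
reproduce characteristics-table and prevalence-change arithmetic.
`location_days()` does leap-aware location-day accounting.

Published-table percentages are reproduced with *half-up* rounding at one
decimal (`round_half_up()`), because R's banker's rounding (`round()`)
disagrees with standard table conventions at exact .05 boundaries.

## The synthetic generator

`simulate_weather()` produces daily regional temperature as a seasonal
sinusoid (mean 27 °C, amplitude 4 °C, peak near day-of-year 330) plus AR(1)
noise (coefficient 0.7, innovation SD 1.5 °C) plus warm-season heat episodes
(Poisson number per year, 3–7 day duration, +8 °C peak anomaly by default).
Dewpoint follows temperature minus a seasonally varying depression so that
derived humidity is realistic for a tropical/arid mix. Counts are generated
per region-day as Poisson with a log-linear mean combining baseline rate,
day-of-week multipliers, the true exposure rate ratios, a holiday effect,
and an optional PM2.5 slope; `simulate_ed_records()` expands counts into a
line list with demographic mixtures. Every component draws from its own
seeded stream (`stream_seed()`), so results are reproducible regardless of
the surrounding RNG state.

One genuine interaction is worth knowing: episodes must stay *sparse*
relative to the climatology percentile. If episode days occupy more than
about 5 % of the reference period, they inflate $T_{95}$ and thereby
redefine the climatology they are measured against, and weak episodes stop
registering as heatwaves. This is faithful to how the EHF behaves on real
warming series, not an artefact; the generator's defaults and the test
suite's property checks respect it.

Limits: the generator is stationary apart from the episodes (no long-term
warming trend), uses one shared parameter set across regions (regions differ
only by RNG stream), and draws demographics independently of exposure, so it
cannot simulate confounding by population composition. PM2.5 can optionally
be made heatwave-dependent (`confound_calendar`) to study adjustment.

`make_fixture()` writes small, self-describing CSV fixtures ("tiny", "null",
"powered") with a JSON manifest that records the generating seeds and true
rate ratios; `run_pipeline()` runs the full chain (detection → record
parsing → aggregation → fit) on such a directory and writes deterministic
outputs.

## Numerical choices

- **Percentiles** use `stats::quantile` type 7 (the R default, linear
  interpolation). This is the single convention used for both $T_{95}$ and
  $\mathrm{EHF}_{85}$.
- **Rolling means** use cumulative sums ($O(n)$), which agree with naive
  summation to ~$10^{-12}$ relative error; tests compare against a naive
  double-loop oracle at `1e-9`.
- **Newton convergence** requires max |score| < 1e-8 or a step below 1e-10,
  with step-halving to guarantee likelihood ascent; failures report the
  likelihood trace.
- **Gamma trend fits** tighten `glm.control(epsilon = 1e-12)` so noise-free
  exponential counts recover the generating slope to better than 1e-6.
- **IRSD banding** supports the two published scheme variants
  (`"deciles137"`: most disadvantaged = decile ≤ 3, most advantaged ≥ 7;
  `"deciles136"`: ≥ 6), which differ only in where decile 7 falls.
- **Timezone**: daily aggregation of sub-daily fields uses a fixed UTC+9:30
  offset by default (Northern Territory, no daylight saving); partial first
  and last local days are dropped and logged.

## Assumptions and limitations

The case-crossover design estimates short-term (within-month) associations
only; effects operating at seasonal scales are absorbed by the strata.
Exposure misclassification from assigning residents to their home region is
not modelled. The quasi-Poisson variance is a working assumption — the
dispersion calibration tests show it is well calibrated for equidispersed
and variance-$2\mu$ data, but heavier-tailed count processes would need a
different variance model. Wald intervals rely on large within-stratum
information; with very sparse counts (well under one event per day) the
design can separate, which the fitter reports rather than silently
extrapolating.
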