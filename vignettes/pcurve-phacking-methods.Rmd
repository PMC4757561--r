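---
title: "Why p-curves cannot unmask p-hacking in observational regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why p-curves cannot unmask p-hacking in observational regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phackcurve)
```

## The scientific question

The p-curve — the distribution of statistically significant p-values across a
set of estimates — has been proposed as a diagnostic for the published
literature: right-skew (mass piled up near zero) is read as evidence of true
effects, while left-skew or a peak just below 0.05 is read as evidence of
p-hacking. That reading rests on the behaviour of p-values in *randomized*
studies, where the estimator of a null effect is unbiased and significant
results arise only by chance.

Observational regression breaks that logic. The analyst chooses which
adjusting variables enter the model, and omitting a variable that both
affects the outcome and correlates with the regressor of interest biases the
coefficient of interest *systematically*. Unlike chance significance, this
omitted-variable bias does not wash out with sample size: as \(n\) grows, the
t-statistic of a biased coefficient diverges and its p-value marches to zero.
A p-hacker who searches across adjustment sets therefore harvests p-values
that look exactly like those of a true effect, and the resulting p-curve is
right-skewed. This package implements the machinery needed to demonstrate,
calibrate and explore that claim.

## The simulation arm

### Data-generating process

Each Monte Carlo iteration draws \((x_i, z_i, \epsilon_i)\) from a
multivariate standard normal with \(\mathrm{Cov}(x, z) = 0.2\) (all variances
one, \(\epsilon\) independent of both, so exogeneity holds by construction)
and forms

\[ y_i = \beta^* x_i + \gamma_i z_i + \epsilon_i , \]

with \(\beta^* = 0\) by default: the true effect of \(x\) is null. Estimating
the simple regression \(y_i = \beta_i x_i + u_i\) — omitting the confounder
\(z\) — produces a slope with expected bias

\[ E[\beta_{\mathrm{ovb}}] = \gamma \,\frac{\mathrm{Cov}(x, z)}{\mathrm{Var}(x)} , \]

implemented in `expected_ovb()`. The confounder coefficient \(\gamma_i\) is
redrawn each iteration from \(\mathrm{Uniform}[0, \gamma^{\max}]\), so the
bias itself is uniform on \([0, 0.2\,\gamma^{\max}]\): a *population* of
studies with heterogeneous unaccounted confounding. The sample size of each
iteration is drawn from a discrete uniform on \([n_{\min}, n_{\max}]\)
(integers, inclusive; the minimum defaults to 50). Every iteration redraws
*all* variables — the conservative design: there is no re-drawing of
\(\gamma\) alone within a fixed dataset, hence no intensive search across
biases.

### Calibrating the confounder strength

Bias strength is most interpretable on the correlation scale. Under the null
DGP with unit variances, \(\mathrm{Var}(y) = \gamma^2 + 1\), so the
population correlation between outcome and regressor of interest is

\[ \rho_{yx}(\gamma) = \frac{\gamma\,\mathrm{Cov}(x,z)}{\sqrt{\gamma^2 + 1}} . \]

Setting \(\rho_{yx}(\gamma) = \rho^{\max}\) and solving gives the exact root

\[ \gamma^{\max} = \frac{\rho^{\max}}{\sqrt{\mathrm{Cov}(x,z)^2 - (\rho^{\max})^2}} , \]

implemented in `calibrate_gamma_max()` (the tests cross-check this closed
form against numerical root-finding and against the correlation realized in
simulated samples of \(10^6\) observations). The attainable correlation is
bounded by \(|\mathrm{Cov}(x,z)|\), so targets at or above it are rejected.
The three canonical bias strengths are \(\rho^{\max} \in \{0.01, 0.05,
0.1\}\) — from one tenth of a conventionally "small" correlation up to a
small one.

### Estimation and inference choices

* **Intercept.** The omitted regression is written without an intercept in
  the theory (all variables are mean zero, so the distinction is
  asymptotically immaterial), but `fit_omitted_regression()` includes one by
  default, matching standard finite-sample t-test conventions; a flag drops
  it.
* **Reference distribution.** Two-sided p-values come from the Student t
  distribution with the residual degrees of freedom, not the normal — the
  difference matters at the minimum sample size of 50.
* **Significance selection.** `p < 0.05`, strict, regardless of sign. The
  simulation's bias is non-negative by construction, so a sign restriction
  would be immaterial here; the specification-search arm restricts sign
  explicitly.
* **Randomness.** Each run takes a single integer seed; all draws then come
  sequentially from one seeded stream, so a run is a pure function of
  (spec, iterations, seed). There is no internal parallelism.
* **Scale.** The full-replication experiment uses 500,000 iterations per
  cell. The package default is 20,000, which already pins bin shares to
  about half a percentage point (binomial standard error); the test suite
  uses 10,000–20,000 per cell and the worked examples below follow suit.

## The p-curve toolkit

`pcurve()` bins the significant p-values into five left-open, right-closed
bins of width 0.01 partitioning \((0, 0.05]\) — the visual granularity of
the standard p-curve figure; the exact published binning is not stated
numerically, and merging adjacent bins of a finer curve reproduces a coarser
one exactly, so nothing hinges on the choice. A value exactly at the
threshold is *not* significant. `skew_summary()` operationalizes the verbal
classifications: `right` when the first bin's share exceeds the last bin's
(by more than a configurable margin, default 0 — the source analyses draw
only qualitative conclusions), `left` for the reverse, `flat` otherwise,
plus a monotone-decreasing flag. This is a descriptive summary; no
inferential skew test is provided because none is needed for the argument.

## The specification-search arm

The empirical illustration asks the same question with real-world structure:
cross-country growth regressions, where the outcome is annualized real GDP
per-capita growth 1960–1996, the variable of interest is malaria prevalence
in 1966, and 15 candidate adjusters (openness, fertility, initial GDP,
schooling, life expectancy, political rights, population, tropical area,
trade, colonial history, water area, public investment, ...) give the
analyst her degrees of freedom.

1. **Null-outcome construction** (`construct_null_outcome()`). Fit the full
   model (intercept + interest + all 15 adjusters), then rebuild the outcome
   with the interest coefficient forced to zero:
   \(y^{\mathrm{new}} = y - \hat\beta^* \cdot \mathrm{interest}\). The new
   outcome keeps every adjuster's fitted contribution and the original
   residuals, so the data's dependence structure is intact while the true
   effect of interest is *exactly* zero. Refitting the full model on
   \(y^{\mathrm{new}}\) returns an interest coefficient of zero to machine
   precision and unchanged adjuster estimates — both are tested at 1e-10.
2. **Model space** (`enumerate_models()`). The typical growth regression has
   about seven regressors, so each candidate model takes the variable of
   interest plus 6 of the 15 adjusters: \(\binom{15}{6} = 5005\) models, in
   lexicographic canonical order.
3. **Vibration analysis** (`vibration_analysis()`). 100 random country
   samples (without replacement — a *sample of countries* — sizes discrete
   uniform on [50, 99]) times all 5005 models = 500,500 estimates, each
   classified by sign and significance at 0.05, with \(-\log_{10} p\) as the
   transformed p-value for plotting (the reference line at
   \(-\log_{10}\alpha\) has the stated above-the-line-significant property).
4. **Sequential search** (`phack_search()`). Draw a country sample, browse
   the 5005 models in uniformly random order without replacement, keep the
   *first* negative-significant interest estimate, then draw a fresh sample;
   a sample with no hit contributes nothing. Harvesting stops at `n_hacked`
   estimates. A `full_sample` flag repeats the exercise with all 99
   countries every time, isolating specification search from sampling error.

Numerical choices: on a 50-country subsample some adjuster subsets can be
numerically rank deficient. The published procedure is silent on this;
`vibration_analysis()` skips and logs the offending (sample, model) pair,
and `phack_search()` treats it as a non-hit and keeps browsing. The search
is bounded by `max_attempts` (default 100 × `n_hacked`) and raises a
condition of class `phack_search_exhausted` — carrying the hits found so
far — when a table simply has no harvestable estimates. Column headers are
matched case-insensitively with `.` and `_` interchangeable, since variable
naming conventions differ across distributed versions of such tables.

For speed, the exhaustive and sequential fitters precompute the full-design
cross-products once per country sample and solve each sub-model's normal
equations from sub-matrices (Cholesky); the tests verify this fast path
against the QR path and against `lm()` to 1e-10.

## The synthetic growth table

The real country table cannot be redistributed here, so
`generate_growth_table()` draws tables with the statistical structure the
pipeline assumes: 99 rows; a variable of interest and 15 adjusters from a
multivariate normal with unit variances and a configurable correlation
matrix (exchangeable by default: 0.2 among adjusters, 0.3 between interest
and each adjuster); an outcome
\(2 + \beta^* \cdot \mathrm{interest} + \sum_j \delta_j \mathrm{adj}_j +
\mathcal{N}(0, 1)\) with \(\beta^* = 0\) — a known, exactly null effect with
live confounding paths. The default \(\delta\) sets the first 8 coefficients
to magnitudes decaying geometrically from 0.5 with alternating signs.

Two frozen flavors serve the tests (`default_growth_spec()`):

* **null-effect** — calibrated once so that specification search finds
  negative-significant estimates at a workable rate: adjusters 1–2 are
  strong negative confounders (correlation 0.5 with the interest variable,
  \(\delta = -0.45\)), adjuster 3 a strong positive one (0.45, \(\delta =
  0.4\)), the rest weakly correlated (0.1) with small mixed-sign
  coefficients. Since only \(\binom{13}{4}/\binom{15}{6} \approx 14\%\) of
  models include both negative confounders, most specifications carry a
  negative omitted-variable bias of roughly 0.2–0.5, yielding
  negative-significant shares on the order of 5–60% of fits depending on the
  realized table, with all four sign-by-significance cells typically
  populated.
* **no-negative-hit** — all \(\delta_j > 0\) with positive
  interest–adjuster correlation, so every omitted-variable bias on the
  interest coefficient is positive: the guaranteed-failure fixture for the
  search's exhaustion path.

What the generator does *not* emulate: the real table's marginal
distributions (colonial-history indicators are binary in reality, continuous
here — the pipeline responds only to correlation structure), its units, its
country identities, and its exact covariance matrix. Tests passing on
synthetic tables therefore establish the *mechanics* (exact null, exhaustive
enumeration, selection logic, right-skew of harvested p-curves), not the
real table's published point values, which require the original data placed
at `inst/extdata/sala_i_martin_growth.csv`.

## Worked example at desk scale

```{r, fig.width = 6, fig.height = 4}
spec <- dgp_spec(rho_max = 0.1, n_max = 10000)
sim <- run_ovb_simulation(spec, iterations = 5000, seed = 1)
summary(sim)
plot(sim)
```

Even with a maximum expected correlation of only 0.1 — entirely due to
confounding — most significant p-values land in the \((0, 0.01]\) bin: a
right-skewed p-curve from a pure null.

```{r}
tab <- generate_growth_table(default_growth_spec("null-effect"), seed = 42)
nt <- construct_null_outcome(tab)$table
hacked <- phack_search(nt, hacking_config(n_hacked = 2000, seed = 11))
summary(hacked)$skew
```

## Known limitations

* Only omitted-variable bias is modelled; simultaneity, measurement error
  and functional-form misspecification — which bias estimates in the same
  asymptotic way — are out of scope, as are experimental p-hacking
  mechanisms (optional stopping, outcome switching).
* The skew classification is a reasonable operationalization of a verbal
  concept, not a canonical definition, and carries no inferential error
  control.
* The exchangeable-correlation synthetic default is transparent but
  unrealistic in detail; users wanting closer mimicry should supply a full
  correlation matrix estimated from data they hold.
* Sequential draws from one RNG stream mean reproducibility is tied to the
  iteration order; the package does not parallelize internally.
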