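---
title: "Benchmarking difference-in-differences estimators on state-year panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking difference-in-differences estimators on state-year panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(didbench)
```

## The problem

State-level policy evaluations with annual panel outcomes — the motivating
case is opioid-overdose mortality rates across the 50 US states — almost
universally use a difference-in-differences (DID) design, but the statistical
model behind that design varies widely: classic two-way fixed effects (TWFE),
TWFE with state-specific linear trends ("detrended"), autoregressive (AR)
models with a lagged outcome, and GEE with a working correlation structure;
each crossed with link functions, analytic population weights or offsets, and
standard-error corrections. These choices matter enormously for bias, error,
and the reliability of significance tests, because state mortality panels are
right-skewed, strongly autocorrelated within state, and offer only 50
clusters of which sometimes a single one is treated.

`didbench` provides a controlled laboratory for these choices. It simulates
balanced state-by-year panels with *known*, injected policy effects and
measures how every model cell in the benchmark grid recovers them. Because
real vital-statistics mortality panels are restricted data, the package
includes a synthetic baseline generator that emulates their salient
statistical structure; any user panel in the same long CSV format can be
substituted.

## Models

All models regress an outcome for state $i$ in year $t$ on a policy exposure
$A_{it} \in [0,1]$ plus a time-varying covariate vector $X_{it}$
(unemployment rate by default):

* **TWFE**: $g(Y_{it}) = \alpha A_{it} + \beta X_{it} + \rho_i + \sigma_t +
  \varepsilon_{it}$ with state effects $\rho_i$ and year effects $\sigma_t$.
* **Detrended**: TWFE plus state-specific linear slopes $\omega_i t$ (one
  state's slope is absorbed by the year effects; the centered panel index is
  used as the time variable). The slopes are built as explicit columns for
  states $2..n$, which keeps the design full-rank — tests verify the policy
  coefficient is identical to the unrestricted `state:t` parameterization.
* **AR**: $g(Y_{it}) = \alpha (A_{it} - A_{i,t-1}) + \beta X_{it} +
  \gamma Y_{i,t-1} + \sigma_t + \epsilon_{it}$. The policy term is
  *change-coded*: the lagged outcome makes this a model for outcome changes,
  and an effect-coded policy term is known to be badly biased there (a
  property test demonstrates this on data generated from the change model).
  No state effects are included; the lag carries state-level persistence.
  The lagged outcome enters on the link-native scale (lagged rate for the
  linear link, lagged log-rate for log-scale links), keeping the predictor
  commensurable with the outcome. The first panel year is dropped.
* **GEE**: linear marginal model with year effects, clustered by state with
  an AR(1) working correlation $R_{t,m} = \rho^{|t-m|}$, fitted by iterated
  estimating equations with a moment update for $\rho$ (iteration cap 100)
  and reported with the robust (Liang–Zeger) sandwich SE.

Link functions: linear (crude rate per 100,000), log-linear (log rate by
least squares), Poisson, and negative binomial (counts with offset
$\log(\text{population}/10^5)$, so coefficients are log incidence-rate
ratios; NB dispersion estimated by maximum likelihood). Linear and
log-linear models are run unweighted or population-weighted (weighted least
squares on the transformed outcome); count models are never weighted.
Zero rates under log transforms are replaced by the continuity-corrected
$0.5/\text{population} \times 10^5$, with occurrences counted and reported —
zero-death state-years do occur in small synthetic states.

Standard errors: model-based (`none`), Huber/HC1 sandwich, and
cluster-robust CR1 (factor $G/(G-1)\cdot(n-1)/(n-p)$) by state, with
p-values from a normal reference for the first two and a $t_{G-1}$ reference
for the cluster estimator. These small-sample scalings are the common
defaults; the sandwich estimators themselves are verified in tests against
brute-force matrix computations.

## Synthetic baseline generator

`generate_baseline()` draws a no-policy panel whose structure mirrors the
targets a state opioid-mortality panel would exhibit. For state $i$, year
index $t = 1..T$:

$$\log r_{it} = a_i + (b + d_i)(t - 1) + e_{it}, \qquad
  e_{it} = \rho\, e_{i,t-1} + \eta_{it}$$

with heterogeneous state levels $a_i$, a rising national trend
$b = \log(1.12)$ per year, heterogeneous slopes $d_i$, and stationary AR(1)
log-rate noise ($\rho = 0.8$, innovation sd $0.12$). Deaths are negative
binomial (gamma–Poisson) with mean $r_{it}\,\mathrm{pop}_i/10^5$ and
dispersion 50, producing overdispersed counts and occasional zero-death
years in small states; realized crude rates are recomputed from the drawn
counts. Populations are constant per state, log-uniform over
$10^{5.7}$–$10^{7.6}$ (about 0.5M–40M, two orders of magnitude).
Unemployment is an independent stationary AR(1) (mean 5.5, sd 1.0,
autocorrelation 0.7): by construction there is no confounding, matching a
randomized placebo-law design. All parameters are overridable; none are
fitted to any real series, and the defaults should be read as a plausible
epidemic-era panel, not as estimates.

Two measurement subtleties are worth knowing:

* *Autocorrelation is measured on the latent surface.* The generator carries
  its latent log-rate alongside the realized counts. Count noise attenuates
  the lag-1 correlation of realized log rates substantially (for a small
  state with a dozen deaths the multiplicative noise variance rivals the
  AR noise variance), so `summarize_baseline()` reports the pooled lag-1
  autocorrelation of detrended latent log rates — which recovers
  $\rho$ to within $\pm 0.05$ at 10,000 state-years — and the attenuated
  realized-rate version alongside.
* *Deterministic mode.* `generate_baseline(cfg, deterministic = TRUE)`
  switches off every noise source and sets rates exactly on the trend curve,
  giving the noise-free limit used by exact-recovery tests (its rates are
  deliberately not re-rounded through counts, so the strict rate–count
  consistency check flags such panels).

What passing tests on this generator do *not* show: real mortality panels
have co-moving states (national shocks beyond a shared trend), policy
co-adoption, reporting artifacts, and population drift. Conclusions here are
about estimator behavior under the stated structure, not about any actual
policy.

## Policy simulation

A simulated condition is (number of treated states $k$, effect size class,
sign, phase-in). Treated states are drawn uniformly; enactment year is
uniform on the window leaving at least three full years on both sides
(2002–2013 for a 1999–2016 panel) and the month uniform on 1–12, with the
policy starting on the first of the month. Instantaneous coding sets the
enactment-year exposure to the fraction of the year in effect,
$(13 - \text{month})/12$, and 1 thereafter; the 3-year phase-in ramps
effectiveness linearly by month, reaching 1 exactly 36 months after
enactment, annualized as the mean of the 12 monthly values. The same coding
is used for data generation and analysis.

Effect sizes are defined on the multiplicative scale
($s = \pm 5\%, \pm 15\%, \pm 25\%$), injected as
$Y^{(1)} = Y^{(0)}(1 + A s)$ for log-scale models. Linear models receive an
additive per-100,000 effect $\alpha_{\text{linear}}$ *calibrated* so its
implied national excess deaths match the multiplicative condition — for one
assignment this reduces to $s$ times the exposure- and population-weighted
mean baseline rate, averaged empirically over assignments
(`calibrate_alpha_linear()`). Scaling the injected effect linearly in the
fractional exposure makes the step and phase-in codings nest. Deaths are
re-derived from modified rates and rounded so count models keep integer
outcomes; additive injections that would push a rate below zero are clamped
at zero and counted.

## Metrics

Let $\hat\alpha_{k,\text{pos}}$ and $\hat\alpha_{k,\text{neg}}$ be estimates
from matched positive/negative arms with truths $\alpha_{\text{pos}} =
-\alpha_{\text{neg}}$. Directional bias averages the error over both arms;
magnitude bias folds the sign first, isolating systematic
exaggeration/attenuation (estimates of $+0.4/-0.4$ against truth $\pm 0.3$
give magnitude bias $+0.1$). Both are also standardized to national annual
excess deaths (linear effects via total population; log effects via
$(e^{\alpha}-1)$ times mean annual baseline deaths) and expressed as a
percentage of the condition's expected excess. RMSE, Type I error (fraction
of null p-values below 0.05), and the calibrated correct-rejection rate
complete the set. The SE correction factor — the empirical 95th percentile
of $|t|$ under the matching null cell divided by 1.96, computed per
(model, SE method, k, phase-in) cell, the strictest granularity — pins each
cell's Type I error at exactly the nominal level before power is compared
across models, so models that understate their uncertainty get no free
power. Non-converged fits are excluded everywhere and counted.

## Orchestration and reproducibility

`experiment_config()` + `run_grid()` run the factorial grid. Child seeds are
derived by hashing (master seed, condition key, simulation index), so every
model sees the same simulated data within a simulation, and adding models or
conditions never changes another cell's random stream (a test verifies
byte-identical estimates between joint and separate runs). By default each
simulation redraws the baseline panel — a true Monte Carlo over the
generator. `fixed_baseline = TRUE` instead reuses one panel and redraws only
assignments, reproducing the placebo-law design used when a single observed
outcome history is available; the figure-style patterns driven by
idiosyncrasies of a fixed panel (e.g. the collapse of weighted-TWFE percent
bias as $k$ grows from 1 to 30) appear in that mode. Estimates are archived
per condition as long CSVs so metrics can be recomputed without
re-simulation, and an existing archive is reused on re-run.

## Numerical and design choices

* Enactment is anchored to the first day of the drawn month; exposure
  fractions follow.
* The detrended time variable is the centered panel index; calendar years
  are labels only.
* GEE declares non-convergence after 100 iterations; its working
  correlation is clamped to $(-0.99, 0.99)$.
* p-value references (normal vs $t_{G-1}$) and sandwich scalings (HC1/CR1)
  are conventional defaults, stated above, not tuned.
* A single treated state is allowed (it is one of the canonical conditions);
  a single *cluster* makes the cluster sandwich degenerate and is reported
  as `NA` rather than raised.
* The lag-order diagnostic (`ar_lag_diagnostics()`) pools within-state
  autocovariances and converts them to partial autocorrelations by
  Durbin–Levinson; the suggested order is the largest lag above a guidance
  band (default $1.96/\sqrt{n}$). Note the band and the estimator's noise
  shrink at the same $1/\sqrt{n}$ rate, so spurious high-lag blips retain a
  roughly constant ~5% chance per lag at any sample size; for automated
  decisions a fixed band such as 0.1 is steadier.

## Scenario choices behind the headline checks

The package's own acceptance checks run at desk scale (250–1000 simulations
per check rather than the canonical 5000; `n_sims` is configurable):

* *Type I error*: the unadjusted linear AR model holds ≤ 6% size under
  placebo policies with 15 treated states on default autocorrelated
  baselines. Unadjusted TWFE, for contrast, rejects almost half the time,
  and only its cluster-robust version returns to the vicinity of 5%.
* *Null RMSE ordering*: AR < detrended ≤ TWFE among unweighted linear
  models on default baselines — the same ordering, and strikingly similar
  magnitudes, as reported for real opioid-mortality panels.
* *Parameter recovery* uses a trend-free (`national_growth = 1`,
  `state_slope_sd = 0`), low-noise configuration. This is deliberate: on
  the default multiplicative-trend baseline the AR-in-levels model is *not*
  correctly specified — its lag coefficient tracks the growth rate
  ($\hat\gamma \approx 1.16$ under a 12%/yr trend) and a permanent additive
  level shift misfits by roughly 3% regardless of how small the noise is.
  That misspecification bias is a genuine finding (the benchmark's bias
  metrics surface it), but the recovery check is about correctly specified
  models, so it runs where all three linear families are correct and all
  recover the truth within 3 Monte-Carlo standard errors.

## Known limitations

Treatment effects are constant across states and time; assignment is always
unconfounded; no repeal, no staggered-heterogeneity-robust estimators, no
synthetic-control or doubly-robust extensions, no Bayesian fitting, and no
random-effects models. The Arellano SE variant is omitted. These are scope
decisions, not oversights; several are natural extensions of the condition
grid.
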