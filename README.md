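# didbench

Monte Carlo benchmarking of difference-in-differences (DID) estimators for
state-level policy evaluation.

## Why

Evaluations of state policies against annual panel outcomes — opioid-overdose
mortality being the motivating, high-stakes example — almost always use a DID
design, but implement it with very different statistical models: classic
two-way fixed effects (TWFE), TWFE with state-specific linear trends
("detrended"), autoregressive (AR) models with a lagged outcome and a
change-coded policy term, and linear GEE with an AR(1) working correlation;
each crossed with link functions (linear, log-linear, Poisson, negative
binomial), population weighting or offsets, and standard-error estimators
(model-based, Huber/HC1, cluster-robust/CR1). With only 50 states, skewed and
strongly autocorrelated outcomes, and sometimes a single treated state, these
choices drive bias, error, and the trustworthiness of significance tests.

`didbench` is a laboratory for those choices: it simulates balanced
state-by-year panels with **known injected policy effects** and measures how
every cell of the model grid recovers them. The core models are, with
$A_{it}$ the policy exposure, $\rho_i$ state effects and $\sigma_t$ year
effects:

- TWFE: $g(Y_{it}) = \alpha A_{it} + \beta X_{it} + \rho_i + \sigma_t + \varepsilon_{it}$
- Detrended: TWFE $+\ \omega_i t$ (state-specific linear slopes)
- AR: $g(Y_{it}) = \alpha (A_{it} - A_{i,t-1}) + \beta X_{it} + \gamma Y_{i,t-1} + \sigma_t + \epsilon_{it}$
- GEE: $g(Y_{it}) = \alpha A_{it} + \beta X_{it} + \sigma_t + \zeta_{it}$, working correlation $R_{t,m} = \rho^{|t-m|}$

Performance is summarized by directional bias, magnitude bias, RMSE, Type I
error, and correct-rejection rates after a per-cell SE calibration that pins
Type I error at the nominal level.

Because real vital-statistics mortality panels are restricted, the package
ships a synthetic baseline generator emulating their structure (right-skewed
crude rates, within-state lag-1 autocorrelation 0.8, a rising national trend,
heterogeneous state levels and slopes, overdispersed counts, populations
spanning two orders of magnitude, an unemployment covariate). Any panel in
the same long CSV format (`state, year, population, deaths, crude_rate,
covariates...`) can be used instead via `read_panel()`.

## Worked example

```r
library(didbench)

panel <- generate_baseline(baseline_config(seed = 1))   # 50 states x 18 years
s <- summarize_baseline(panel)
# skewness 4.71 | latent lag-1 autocorr 0.53 | pop ratio 72

# additive per-100k effect matching a +15% multiplicative effect in national
# excess deaths on this panel:
alpha <- calibrate_alpha_linear(panel, s = 0.15, k = 15, n_assign = 200)
# 2.365 per 100,000

asg <- assign_policy(panel, k = 15, seed = 7)           # random placebo states
ex  <- code_exposure(asg, panel, "instantaneous")       # fractional first year
sim <- inject_effect(panel, ex,
                     effect_spec("medium", "+", alpha_linear = alpha),
                     "additive_rate")

for (id in c("twfe_linear_unweighted", "detrended_linear_unweighted",
             "ar_linear_unweighted")) {
  f <- fit_model(sim, id)
  cat(sprintf("%-28s alpha_hat = %6.3f  se(cluster) = %5.3f  p = %.4f\n",
              id, f$alpha_hat, f$se[["cluster"]], f$p[["cluster"]]))
}
#> twfe_linear_unweighted       alpha_hat =  4.448  se(cluster) = 4.755  p = 0.3541
#> detrended_linear_unweighted  alpha_hat =  2.715  se(cluster) = 1.832  p = 0.1449
#> ar_linear_unweighted         alpha_hat =  2.079  se(cluster) = 0.609  p = 0.0013
```

The true injected effect is 2.365 per 100,000. On this single draw the TWFE
estimate is badly off (and insignificant), the detrended model does better,
and the AR model is close and precise — the single-draw version of the
benchmark's systematic finding that AR models dominate on autocorrelated
rate panels.

Full factorial experiments run through a config:

```r
cfg <- experiment_config(
  baseline = baseline_config(seed = 1),
  models = c("ar_linear_unweighted", "twfe_linear_unweighted"),
  k = c(5, 15), size_classes = c("null", "small"),
  phase_ins = "instantaneous", n_sims = 200, seed = 42
)
res <- run_grid(cfg, "results_dir")
summarize_run("results_dir")   # Type I, RMSE, % bias, rejection-rate sections
```

A thin CLI wraps the same functions: `exec/didbench generate-baseline | validate | run | summarize`
(see the file header for the YAML config keys).

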