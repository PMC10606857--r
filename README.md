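# robmclr

Robust estimation for **multinomial logistic regression with circular
covariates** (MCLR). Angular predictors — wind direction, leaf
inclination, hour of day on the 24 h clock — enter the linear predictor
through their unit-circle embedding: for `d + 1` response categories
and `k` angles `u = (u_1, ..., u_k)`,

```
pi_j(beta | u) = exp(eta_j) / (1 + sum_s exp(eta_s)),   j = 1, ..., d
eta_j = beta_j0 + sum_l [ beta_jl^(1) cos(u_l) + beta_jl^(2) sin(u_l) ]
```

with the last category as reference. Instead of maximum likelihood —
efficient but badly distorted by a few mislabelled observations — the
package estimates `beta` by the **minimum density power divergence
estimator (MDPDE)** with tuning parameter `alpha >= 0`:

```
beta-hat(alpha) = argmin  n^-(1+a) sum_{i,j} [ n_i^(1+a) pi_ij^(1+a)
                  - (1 + 1/a) nu_ij n_i^a pi_ij^a + (1/a) nu_ij^(1+a) ]
```

over the `I` covariate patterns with counts `nu_ij` and sizes `n_i`.
`alpha = 0` recovers the MLE exactly; growing `alpha` downweights
cells the model finds implausible (influence scales like `pi^alpha`),
trading a little efficiency on clean data for stability under
contamination. Standard errors come from the sandwich covariance
`Psi^-1 Omega Psi^-1 / n` of the estimating equations; `alpha` in
`(0, 0.4]` is a good default under suspected mild contamination.

The package is tidyverse-native: grouped data are tibbles, fits have
`tidy()` / `glance()` methods, results plot with `autoplot()`. It also
ships circular samplers (uniform, von Mises, spherical normal) and a
Monte-Carlo engine for contamination studies. Intended users:
statisticians and quantitative ecologists / meteorologists modelling
categorical outcomes against directional measurements.

## Worked example

Simulate grouped data from a 3-category model with one circular
covariate, contaminate 10% of the observations into category `"low"`,
and compare the MLE with a robust fit:

```r
library(robmclr)
set.seed(1)

beta_true <- c(0, 2, 2, 0.2, 2.5, 1.5)
dat <- simulate_mclr_data(beta_true, d = 2, I = 50, ni = 10,
                          labels = c("low", "mid", "high"))
dat_out <- contaminate(dat, rate = 0.1, target_category = 1)

fit_mle <- mclr_fit(dat_out, alpha = 0)
fit_rob <- mclr_fit(dat_out, alpha = 0.4)
tidy(fit_rob)
#> # A tibble: 6 × 5
#>   term            estimate std.error statistic  p.value
#>   <chr>              <dbl>     <dbl>     <dbl>    <dbl>
#> 1 low:(Intercept)   0.374      0.159     2.34  1.90e- 2
#> 2 low:cos(u1)       1.50       0.224     6.69  2.27e-11
#> 3 low:sin(u1)       1.62       0.191     8.49  2.07e-17
#> 4 mid:(Intercept)  -0.0393     0.177    -0.222 8.24e- 1
#> 5 mid:cos(u1)       2.69       0.264    10.2   3.03e-24
#> 6 mid:sin(u1)       1.43       0.214     6.67  2.62e-11
```

Each row is one coefficient of a non-reference category (`low`, `mid`)
with its sandwich standard error and Wald test. The contamination
inflates the `low` intercept (truth 0); the robust fit pulls it back
relative to the MLE. Scoring both fits by the mean absolute error of
fitted probabilities against the truth over the clean patterns:

```r
mae_probabilities(fit_mle$beta, beta_true, dat)   # 0.0547
mae_probabilities(fit_rob$beta, beta_true, dat)   # 0.0540
accuracy(fit_mle, dat)                            # 0.658
```

Real (ungrouped) data enter through `group_angular()` /
`read_angular_csv()` — one row per observation, angles in degrees or
radians, the *last* category label declared is the reference — and
fitted models persist as JSON via `write_mclr_fit()` for later
`classify()` / `predict()` calls. `mclr_fit_grid()` fits a whole
`alpha` path; `run_simulation_study()` replicates the
generate–contaminate–refit loop and summarizes MAE per `alpha`.

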