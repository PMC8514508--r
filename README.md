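# lakecs

Fractional-diffusion modelling of caesium-137 decline in closed lakes and
their fish.

## The problem

In a closed lake — little inflow or outflow, sediment–water exchange doing
the work — the ¹³⁷Cs activity concentration after a fallout event declines
with a long tail that a single exponential cannot describe. Monitoring
practice patches this with a two-component decay model (TDM),
`Q₁e^{−k₁t} + Q₂e^{−k₂t}`. `lakecs` implements the mechanistic alternative:
if dissolved radiocesium moves by a random walk with Gaussian jumps and
power-law waiting times (repeated trapping in the sediments), the whole-lake
average follows the fractional-diffusion model (FDM)

```
C(t) = A · E_α(−ξ (t/τ)^α) · exp(−λ_d t),      0 < α < 1,
```

where `E_α` is the Mittag-Leffler function `Σ z^k / Γ(αk + 1)`, `A` the
initial average concentration, `λ_d` the ¹³⁷Cs decay constant, and
`θ = ξ τ^(−α)` the only combination of `ξ` and `τ` the curve depends on.
The law is exponential early and decays as `t^(−α)` late — one shape that
covers both regimes and keeps predicting beyond the fitted window. At
`α = 1` it is plain exponential decay; at `α = 1/2` it reproduces the
Bulgakov sediment-diffusion model `(σ_d/h_w)·e^{z²}erfc(z)·e^{−λ_d t}`.

The package is aimed at environmental radioecologists who need long-horizon
(10⁴-day) predictions of lake-water and fish contamination from short,
irregular, noisy monitoring series. It provides:

* robust evaluation of `E_α(−y)` (power series, Gorenflo integral
  representation, tail asymptotics, automatic dispatch);
* forward models: FDM, TDM/SDM, Bulgakov (exact and approximate forms);
* relative-error Levenberg–Marquardt fitting (`ε² = Σ((C_m − C)/C_m)²`),
  blind-test backtesting, long-horizon prediction, water–fish correlation;
* a continuous-time random-walk Monte-Carlo simulator validating the
  subdiffusive premise (MSD ∝ t^α);
* a synthetic-series generator (truth curve × lognormal noise) standing in
  for monitoring tables that cannot be redistributed.

Everything takes and returns tibbles, with broom-style `tidy()`/`glance()`
and `ggplot2::autoplot()` methods.

## Worked example

Generate a synthetic lake-water series (FDM truth `A = 1256` Bq m⁻³,
`α = 0.62`, `ξ = 5`, `τ = 693` d; 40 samples over days 234–1981; 10%
relative noise), fit both models, and backtest:

```r
library(lakecs)

series <- generate_series(synthetic_spec(noise_sd_rel = 0.1, seed = 42))
fit <- fit_model(series, "fdm")
fit
#> <lakecs_fit> FDM fit, 40 points
#>   epsilon^2 = 0.533939  (converged)
#> # A tibble: 6 × 3
#>   term        estimate fixed
#>   <chr>          <dbl> <lgl>
#> 1 A        981.        FALSE
#> 2 alpha      0.666     FALSE
#> 3 theta      0.0469    FALSE
#> 4 xi         3.65      TRUE
#> 5 tau      693         TRUE
#> 6 lambda_d   0.0000631 TRUE
```

`ε² = 0.53` is the squared relative error over 40 points (≈ 0.12 per point
at 10% noise is the expected floor, plus model–noise interaction); `alpha`
and `theta` are the free shape parameters, while `xi` is derived from
`theta` under the fixed-`tau = 693` reporting convention and `lambda_d` is
the ¹³⁷Cs constant, never fitted. A head-to-head comparison on the same
series gives one `ε²` per model:

```r
compare_models(series, c("fdm", "tdm"))
#> # A tibble: 2 × 7
#>   model epsilon2 n_points converged boundary n_iterations grad_norm
#> 1 fdm      0.534       40 TRUE      FALSE              11  0.000347
#> 2 tdm      0.523       40 TRUE      FALSE              19  0.000164

backtest(series, split_day = 1527, model = "fdm")
#> <lakecs_backtest> FDM, split at day 1527
#>   train: n = 29, epsilon^2 = 0.419796
#>   test:  n = 11, epsilon^2 = 0.120613
```

The backtest trains on days ≤ 1527 and scores the frozen curve on the
held-out 11 later points. Long-horizon prediction from given parameters:

```r
p <- fdm_params(A = 1256, alpha = 0.62, xi = 5, tau = 693)
predict_curve(p, c(0, 1000, 5000, 10000))
#> # A tibble: 4 × 2
#>     day  value
#> 1     0 1256
#> 2  1000   85.3
#> 3  5000   23.6
#> 4 10000   11.1
```

— at day 0 the curve returns `A` exactly; by day 10⁴ the decline is
power-law (`t^(−0.62)`) times radioactive decay, far slower than any
exponential component would allow. `autoplot(fit)`, `autoplot(backtest(...))`
and `autoplot(simulate_msd(...))` draw the standard diagnostic figures.

The CTRW validator, run small:

```r
res <- simulate_msd(ctrw_config(alpha = 0.62, n_particles = 2000, seed = 7))
glance(res)   # fitted MSD exponent ≈ 0.61 — subdiffusion with slope α
```

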