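# mmgrowth

Multi-model Bayesian and frequentist length-at-age growth modelling for
fish and sharks.

## The problem

Growth curves underpin fisheries stock assessment, but the samples they are
fitted to are rarely representative: fishing gear is size selective, so the
youngest or oldest animals — exactly the individuals that anchor the two
biologically meaningful parameters, length-at-birth (*L₀*) and asymptotic
length (*L∞*) — are often missing. Ordinary nonlinear least squares then
produces curves that describe the sampled ages well but extrapolate to
absurd parameter values (lengths-at-birth of 150 cm for an egg-spawning
fish, asymptotic lengths of kilometres).

`mmgrowth` addresses this by fitting growth models by MCMC with informative
priors on *L₀* and *L∞* — two quantities that are usually known from
biology (length-at-birth, maximum observed length) even when the sample
cannot estimate them — while keeping a matched frequentist arm for
comparison, and a gear-selectivity simulator to quantify when the priors
matter.

## The models

Three candidate curves share the (*L₀*, *L∞*) parameterisation, so one
prior set serves all of them:

| model | length at age *a* |
|---|---|
| von Bertalanffy | *Lₐ = L∞ − (L∞ − L₀) e^(−ka)* |
| Gompertz | *Lₐ = L₀ exp( log(L∞/L₀)(1 − e^(−ka)) )* |
| logistic | *Lₐ = (L∞ L₀ e^(ka)) / (L∞ + L₀(e^(ka) − 1))* |

Observed lengths get a normal residual with SD *σ*. Priors:
*L∞* ~ N(μ, s) and *L₀* ~ N(μ, s) truncated to [0, ∞) (half-normal when the
mean is near zero), *k* ~ U(k_min, k_max), *σ* ~ U(0, σ_max). Posteriors are
sampled with JAGS; candidate models are ranked by LOOIC (Pareto-smoothed
importance-sampling leave-one-out cross-validation, computed in-package from
the pointwise log-likelihoods) in the Bayesian arm and by
AIC = n·log(σ²) + 2(p+1) with exp(−Δ/2) weights in the frequentist arm.

## Worked example

Simulate an ageing study in which gear selectivity excludes juveniles
(logistic selectivity, slope 0.7, age-at-50% 12 yr, natural mortality
0.2 yr⁻¹) from a von Bertalanffy truth of *L∞* = 250 cm, *k* = 0.2 yr⁻¹,
*L₀* = 0, with multiplicative length CV 0.5 — then fit both arms:

```r
library(mmgrowth)
sim <- simulate_lengths(scenario = scenario_preset("increasing"), n = 150, seed = 7)
priors <- growth_priors(L_inf_mean = 275, L_inf_sd = 27.5,  # max length ~5-10% above L_inf
                        L0_mean = 0, L0_sd = 1e-3,          # egg-spawner: L0 pinned at 0
                        k_max = 0.5, sigma_max = 200, k_min = 1e-5)
fit <- fit_growth_mcmc(sim$data, "vbgm", priors,
                       mcmc_settings(chains = 4, iterations = 10000, warmup = 5000, seed = 1))
print(fit)
#> Bayesian vbgm growth fit: 4 chains x 5000 retained draws (n = 150)
#>  parameter      mean        sd    median      q2.5     q97.5  rhat   ess
#>      L_inf 2.479e+02 1.445e+01 2.458e+02 2.252e+02 2.831e+02 1.001  3429
#>          k 2.856e-01 1.050e-01 2.701e-01 1.238e-01 4.853e-01 1.001  3749
#>         L0 7.995e-04 6.077e-04 6.739e-04 2.987e-05 2.255e-03 1.000 20052
#>      sigma 1.092e+02 6.262e+00 1.090e+02 9.785e+01 1.224e+02 1.000 11555

fit_growth_nls(sim$data, "vbgm")
#> NLS vbgm growth fit (n = 150)
#>        estimate       se
#> L_inf 288.76407 238.6184
#> k       0.04702   0.2011
#> L0    175.52006  97.5414
#> sigma 107.45697       NA
#>   residual variance (RSS/n): 1.155e+04
```

The posterior mean *L∞* of 247.9 cm sits within one posterior SD of the
generating value (250 cm) and the half-normal prior keeps *L₀* at its true
value of zero, while the free-*L₀* least-squares fit — with no age-0 to
age-8 fish in the sample — invents a 175 cm length-at-birth with a standard
error nearly as large. Model ranking works the same way in both arms:

```r
gomp <- fit_growth_mcmc(sim$data, "gompertz", priors,
                        mcmc_settings(chains = 4, iterations = 10000, warmup = 5000, seed = 1))
compare_models(list(fit, gomp))
#>      model criterion    value    delta     weight pareto_k_max
#> 1     vbgm     LOOIC 1834.755 0.000000 0.95464956    0.1708015
#> 2 gompertz     LOOIC 1840.848 6.093849 0.04535044    0.1951517
```

A command-line interface wraps the same functions
(`exec/mmgrowth fit --data d.csv --models all --linf-mean 275 --out run/`,
plus `simulate`, `compare` and `diagnose` subcommands); every run directory
contains a manifest sufficient to reproduce it bit for bit.

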