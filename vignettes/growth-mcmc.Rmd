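---
title: "Bayesian multi-model length-at-age estimation: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multi-model length-at-age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
the growth models and their shared parameterisation, the prior scheme, the
sampler and its diagnostics, model selection, the frequentist comparator,
and the selectivity simulator — with the reasoning behind every tunable
default and the known limitations of each piece.

## The multi-model framework

Three growth curves are fitted as interchangeable candidates: von
Bertalanffy, Gompertz and logistic. All three are written in terms of
length-at-birth $L_0$ (cm) and asymptotic length $L_\infty$ (cm) rather
than the theoretical age-at-zero-length $t_0$, because $L_0$ and $L_\infty$
carry the same biological meaning in every candidate — the length of a
newborn and the average length of a fully grown individual — whereas $t_0$
has none. The growth completion rate $k$ (yr$^{-1}$) is *not* comparable
between candidates: the same data can yield $k \approx 0.07$ under a von
Bertalanffy fit and $k \approx 0.27$ under a logistic fit, so $k$ values
should never be transplanted across model forms.

At age zero each curve returns exactly $L_0$, and each rises monotonically
to $L_\infty$. Observed lengths are modelled with a homoscedastic normal
residual of SD $\sigma$ (cm), which makes Bayesian and least-squares
estimates directly comparable.

Ages are continuous throughout the fitting code; integer ages appear only
in the sampling simulator, whose observation process is an age-structured
multinomial.

## Priors

* $L_\infty \sim N(\mu, s)$ truncated to $[0, \infty)$ — centre $\mu$ on the
  species' maximum length. Maximum length usually *exceeds* $L_\infty$
  (it is the largest individual ever seen, not the average adult), so this
  prior pulls upward slightly when the data cannot say otherwise; the
  simulation experiments below quantify that pull.
* $L_0 \sim N(\mu, s)$ truncated to $[0, \infty)$ — centre on the known
  length-at-birth. For egg-spawning fishes $\mu \approx 0$ and the
  truncation turns the prior into a half-normal pinned at zero; the default
  SD in that case is $10^{-3}$ cm. For live-bearers (sharks) with
  $L_0 \gg 0$ the truncation is immaterial.
* $k \sim U(k_{\min}, k_{\max})$ and $\sigma \sim U(0, \sigma_{\max})$ —
  deliberately uninformative. The upper bounds must sit *well above* any
  plausible estimate under **every** candidate model (a logistic $k$ can be
  several times a von Bertalanffy $k$); a bound that binds visibly distorts
  the posterior, and a bound that does not bind costs nothing. Whether the
  bounds were adequate can be checked after the fact: the $k$ and $\sigma$
  posteriors should look approximately normal, not piled against an edge.
  $k_{\min}$ defaults to 0; the recovery experiments use $10^{-5}$, which
  keeps the sampler off the degenerate $k = 0$ axis.

The standard-error heuristic implemented by `default_priors()` starts both
normal SDs at 10% of the respective means. Narrower priors weight the
posterior toward the prior (useful with small, biased samples); wider ones
let the likelihood dominate (with rich data the results become
indistinguishable from least squares, a property the test suite checks).

Truncation is implemented by renormalising the normal density on
$[0, \infty)$, not by rejection, so the log-posterior stays smooth.

## Sampling

`fit_growth_mcmc()` specifies the model in the BUGS language and delegates
the kernel to JAGS (via `rjags`). Defaults follow common practice for these
models: 4 chains, 10,000 iterations per chain *including* a 5,000-iteration
warmup (so 5,000 retained per chain), no thinning. The sampler's adaptation
phase (up to 1,000 iterations) is counted inside the warmup budget. Initial
values: $k$ and $\sigma$ start at the midpoints of their uniform supports,
jittered per chain; $L_\infty$ and $L_0$ are drawn from their truncated
priors. Each chain owns a deterministically derived RNG seed, so a fit is
bit-reproducible from `mcmc_settings()` alone — a property the run manifest
of the command-line interface relies on.

The Gompertz and logistic means involve $\log(L_\infty/L_0)$ or a ratio in
$L_0$, so evaluation requires $L_0 > 0$. Proposals below an evaluation
floor of $10^{-6}$ cm are clamped rather than rejected: under a continuous
prior the point $L_0 = 0$ has measure zero, and a near-zero half-normal
prior (the egg-spawner case) must remain fittable for these two curves.

Every retained draw is stored with its **pointwise log-likelihood** row
(one normal log-density per observation), which is what LOOIC consumes;
by construction each row sums to the joint log-likelihood of that draw.

### Diagnostics

* **Split-$\widehat{R}$** (`gelman_rubin()`): each chain is split in half
  and the potential scale reduction factor computed over the half-chains,
  so a single trending chain is caught as disagreement between its own
  halves. The fitting path warns — it does not error — above 1.01, a
  deliberately strict cutoff for these four-parameter models.
* **Effective sample size** via `coda::effectiveSize`.
* **Autocorrelation** (`autocorrelation_check()`): per-parameter ACF
  averaged over chains; a lag-1 autocorrelation above 0.3 flags the fit.
  The remedy is `thin_draws()` *plus longer chains* — thinning alone
  discards information and is only worthwhile when memory or downstream
  cost matters; the 0.3 threshold marks where the nominal draw count
  overstates the information content by roughly a factor of two.

## Model selection

**Bayesian arm.** Candidates are ranked by
$\mathrm{LOOIC} = -2\,\widehat{\mathrm{elpd}}_{\mathrm{loo}}$, the
leave-one-out expected log predictive density estimated by Pareto-smoothed
importance sampling from the stored pointwise log-likelihoods. The
smoothing follows the standard published algorithm: per observation, the
importance ratios $1/p(y_i \mid \theta_s)$ are formed; the largest 20% are
replaced by expected order statistics of a generalised Pareto distribution
fitted to their exceedances (Zhang–Stephens profile posterior method, with
a weak shrinkage of the shape toward 0.5), capped at the largest raw
ratio; the fitted shape $\hat{k}$ is reported per observation and a
warning raised above 0.7, the point beyond which the importance estimate's
variance is effectively unbounded. The implementation is validated in the
test suite against exact leave-one-out computed by analytic refits of a
conjugate normal-mean model.

**Frequentist arm.** $\mathrm{AIC} = n \log \hat\sigma^2 + 2(p + 1)$, with
$\hat\sigma^2 = \mathrm{RSS}/n$ — the *maximum-likelihood* residual
variance, not the unbiased $\mathrm{RSS}/(n-p)$ — because that is the
variance under which $n \log \hat\sigma^2$ is the concentrated
log-likelihood; $p$ counts the free curve parameters and the $+1$ counts
$\hat\sigma^2$ itself.

Both criteria convert to weights $w_i \propto \exp(-\Delta_i/2)$. Ties in
the ranking keep the order in which models were supplied. A non-converged
least-squares fit enters the table with an infinite criterion value and
weight zero rather than being dropped.

## The frequentist comparator

`fit_growth_nls()` minimises the residual sum of squares with a
Levenberg–Marquardt optimiser (`minpack.lm::nlsLM`), from scale-free
starting values ($L_\infty^{(0)} = 1.1 \max \ell$,
$L_0^{(0)} = \max(\min \ell / 2, 10^{-3})$, $k^{(0)} = 0.1$), with up to
five jittered restarts before declaring non-convergence — reported as a
flag, never an exception, because "did not converge" is itself a result
worth tabulating. Parameters are bounded below ($L_\infty > 0$,
$L_0 \ge 0$, $k \ge 10^{-5}$); when a pathological dataset drives the
optimum toward the $k \to 0$ ridge (where the curve degenerates to a
straight line and $L_\infty$ diverges), the bound is where it comes to
rest, and the absurd estimates are reported as found — exposing them is
the comparator's purpose.

Confidence bands use nonparametric **case resampling**: records resampled
with replacement, the model refitted per replicate (failed refits dropped
and counted; more than 50% failures is an error), and per-age percentile
bounds taken over the replicate curves. The default of 1,000 replicates
with percentile intervals is conventional; residual resampling was
rejected because the residuals are strongly heteroscedastic under the
multiplicative-error data this package is designed around.

## The selectivity simulator

`simulate_lengths()` emulates an ageing study biased by gear selectivity:

1. **Population structure.** Survivorship declines exponentially,
   $l_a = e^{-Ma}$, with natural mortality $M = 0.2$ yr$^{-1}$ by default.
   The default maximum age of 30 leaves $l_{30} = e^{-6} \approx 0.25\%$ of
   the cohort, effectively exhausting it.
2. **Gear selectivity** $S_a$: increasing logistic
   $1/(1+e^{-\mathrm{slope}(a-a_{50})})$, decreasing logistic (its mirror),
   a Gaussian dome scaled to peak 1, or uniform. The three shipped presets —
   increasing (slope 0.7, $a_{50}$ 12), decreasing (slope 1, $a_{50}$ 1.5),
   dome (mean 10, SD 2) — are the standard recovery-experiment
   configurations.
3. **Ages** are drawn multinomially over the integers $0..\max$ with
   probability $\propto l_a S_a$. Integer ages are the only reading
   consistent with a multinomial observation process.
4. **Lengths** are drawn from $N(\bar L_a,\; \bar L_a \sigma_m)$ where
   $\bar L_a$ is the generating curve (von Bertalanffy with
   $L_\infty = 250$, $k = 0.2$, $L_0 = 0$ and $\sigma_m = 0.5$ by default):
   a multiplicative error whose SD grows in proportion to mean length,
   mimicking the accumulation of individual growth variation with age.
   Negative draws are redrawn; with $L_0 = 0$, age-0 records are exactly 0.
5. **Seeding.** The root seed is split into one stream for age sampling and
   one for length noise, so the two stages are individually reproducible.

The dome's peak-1 scaling is inconsequential (probabilities are
renormalised) but fixed for reproducibility.

**What the simulator does not emulate** — and hence what passing recovery
tests do and do not show about real data: there is no persistent
individual growth heterogeneity (each length is an independent draw around
the population curve, not a coherent individual trajectory), no ageing
error, no length-based (as opposed to age-based) selectivity, no
time-varying mortality, and no measurement rounding. Recovery under this
generator demonstrates robustness to *sampling* bias, not to these other
data pathologies.

**A known bias of the positivity rule.** Redrawing negative lengths
samples from a zero-truncated normal, which raises the realised mean
length at every age by $\approx 2.8\%$ when $\sigma_m = 0.5$ (the
truncation point sits $2\sigma$ below the mean at every age, because the
SD is proportional to the mean). Two measured consequences under the
default generator: posterior means of $L_\infty$ centre near 257 rather
than 250, and the 95% credibility interval for $L_\infty$ covers the
generating value in roughly 80% of uniform-selectivity replicates at
$n = 150$ rather than at nominal rates — the test suite's calibration
check documents this shortfall rather than hiding it. At realistic CVs
(5–15%) negative draws are essentially impossible and the bias vanishes;
it is an artefact of the deliberately extreme $\sigma_m = 0.5$ stress
conditions combined with the positivity constraint on emitted lengths.

## Choices made where the design was open

* **Sampler backend.** Any kernel meeting the reproducibility and
  recovery contracts would do; JAGS was chosen because it is the
  field-standard Gibbs/slice backend available as an R package, it handles
  the truncated priors natively, and it satisfies bit-reproducibility via
  per-chain seeds. The model specification, pointwise likelihood,
  diagnostics and LOOIC are all implemented in this package, so the
  backend is replaceable.
* **Iterations include warmup.** "10,000 iterations with 5,000 warmup"
  is interpreted as 5,000 retained draws per chain.
* **$\sigma_{\max} = 200$ cm in the recovery experiments.** Under the
  default generator the residual SD approaches
  $\sigma_m L_\infty = 125$ cm, so the customary bound of 100 would bind.
  Posterior means shift by under 0.5% across
  $\sigma_{\max} \in \{100, 200, 400\}$, but an unbound prior is the
  framework's own stated guidance.
* **Problem sizes in the test suite.** Unit tests run 2 chains of
  1,200–3,000 iterations; the recovery experiments use the full 4 × 10,000
  settings where the experiment is about the posterior itself and reduced
  settings where it is about a qualitative contrast or a coverage
  proportion (50 calibration replicates at 2 × 2,500). These sizes were
  chosen so the entire suite exercises every code path at meaningful
  precision in a few minutes on one core.
* **Restart jitter and bootstrap defaults** (5 restarts, 1,000 replicates,
  percentile method) are conventional values; none is load-bearing.

## Known limitations

* Homoscedastic normal residuals only; no lognormal or multiplicative
  error structure in the *fitting* path (the simulator's multiplicative
  error is deliberately misspecified relative to the fitted likelihood,
  as a stress test).
* Single-population curves: no hierarchical, biphasic, seasonal or
  tag-recapture variants.
* Under increasing selectivity with the extreme default noise, $k$ is
  weakly identified and its posterior leans on the uniform prior's
  midpoint; the posterior SD (correctly) says so.
* LOOIC requires at least 100 retained draws and all-finite pointwise
  log-likelihoods; observations with Pareto $\hat k > 0.7$ are flagged,
  not silently accepted.
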