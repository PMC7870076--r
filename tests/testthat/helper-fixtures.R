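# Fixtures built in code: additive-noise recovery datasets, the standard
# simulation-study priors, fast MCMC settings for unit tests, and a memoised
# recovery fit shared by several test files.

# Additive-noise length-at-age data on a fixed age grid (the simple recovery
# substrate; the selectivity simulator provides the biased-sampling one).
make_curve_data <- function(kind, L_inf, k, L0, ages, noise_sd = 0, seed = 1) {
  mu <- predict_length(kind, growth_params(L_inf, k, max(L0, 1e-6), 1), ages)
  set.seed(seed)
  y <- mu + stats::rnorm(length(ages), 0, noise_sd)
  y[y < 0] <- mu[y < 0]
  growth_data(ages, y)
}

# Priors of the selectivity recovery experiments.
sim_priors <- function() {
  growth_priors(L_inf_mean = 275, L_inf_sd = 27.5, L0_mean = 0, L0_sd = 1e-3,
                k_max = 0.5, sigma_max = 200, k_min = 1e-5)
}

# Small-but-honest sampler settings for unit tests.
quick_settings <- function(seed = 1, chains = 2, iterations = 3000, warmup = 1500) {
  mcmc_settings(chains = chains, iterations = iterations, warmup = warmup,
                thin = 1, seed = seed)
}

# Recovery fit reused across tests: n = 300 from vbgm(250, 0.2, 0) with
# additive SD-10 noise and uniform age coverage, fitted with the standard
# simulation priors. Memoised so the sampler runs once per session.
.fixture_cache <- new.env(parent = emptyenv())

shared_recovery <- function() {
  if (is.null(.fixture_cache$recovery)) {
    ages <- rep(0:29, length.out = 300)
    d <- make_curve_data("vbgm", 250, 0.2, 0, ages, noise_sd = 10, seed = 42)
    fit <- fit_growth_mcmc(d, "vbgm", sim_priors(), quick_settings(seed = 5))
    .fixture_cache$recovery <- list(data = d, fit = fit,
                                    truth = c(L_inf = 250, k = 0.2, L0 = 0))
  }
  .fixture_cache$recovery
}

# A hand-built fit object holding prescribed per-chain draws, for exercising
# thinning and diagnostics on sequences with known autocorrelation.
fake_fit <- function(chains, data = growth_data(1:3, c(50, 80, 100)),
                     kind = "vbgm") {
  draws <- lapply(chains, function(m) {
    colnames(m) <- c("L_inf", "k", "L0", "sigma")
    m
  })
  log_lik <- lapply(draws, function(m) mmgrowth:::pointwise_log_lik(kind, m, data))
  structure(list(kind = kind, draws = draws, log_lik = log_lik, data = data,
                 priors = sim_priors(),
                 settings = mcmc_settings(length(chains),
                                          2 * nrow(chains[[1]]), nrow(chains[[1]]),
                                          seed = 1),
                 rhat = NULL, ess = NULL),
            class = "growth_mcmc_fit")
}

# AR(1) sequence with given lag-1 coefficient.
ar1 <- function(n, phi, seed = 1, mean = 0, sd = 1) {
  set.seed(seed)
  as.numeric(mean + sd * stats::arima.sim(list(ar = phi), n = n,
                                          sd = sqrt(1 - phi^2)))
}
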