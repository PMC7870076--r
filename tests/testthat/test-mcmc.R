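# Bayesian fitting: recovery, prior limits, draw support, reproducibility,
# thinning and posterior curves.

test_that("posterior means recover the generating parameters on rich data", {
  rec <- shared_recovery()
  sm <- summary(rec$fit)
  est <- setNames(sm$mean, sm$parameter)
  sds <- setNames(sm$sd, sm$parameter)
  expect_lt(abs(est[["L_inf"]] - 250), 2 * sds[["L_inf"]])
  expect_lt(abs(est[["k"]] - 0.2), 2 * sds[["k"]])
  expect_lt(est[["L0"]], 2 * sds[["L0"]] + 0.01)
  expect_lt(abs(est[["sigma"]] - 10), 2 * sds[["sigma"]] + 1)
})

test_that("with one observation and tight priors the posterior sits on the priors", {
  d <- growth_data(10, 150)
  pr <- growth_priors(L_inf_mean = 300, L_inf_sd = 1e-4,
                      L0_mean = 60, L0_sd = 1e-4,
                      k_max = 0.5, sigma_max = 1e6)
  fit <- suppressWarnings(fit_growth_mcmc(d, "vbgm", pr, quick_settings(seed = 2)))
  sm <- summary(fit)
  est <- setNames(sm$mean, sm$parameter)
  expect_lt(abs(est[["L_inf"]] - 300) / 300, 0.01)
  expect_lt(abs(est[["L0"]] - 60) / 60, 0.01)
})

test_that("a flat likelihood returns the (truncated) prior for L0 and L_inf", {
  # one point, enormous sigma_max: likelihood contributes almost nothing
  d <- growth_data(5, 100)
  pr <- growth_priors(L_inf_mean = 280, L_inf_sd = 15, L0_mean = 77, L0_sd = 5,
                      k_max = 1, sigma_max = 1e6)
  fit <- suppressWarnings(fit_growth_mcmc(d, "vbgm", pr, quick_settings(seed = 3)))
  sm <- summary(fit)
  est <- setNames(sm$mean, sm$parameter)
  expect_lt(abs(est[["L_inf"]] - 280) / 280, 0.05)
  expect_lt(abs(est[["L0"]] - 77) / 77, 0.05)
})

test_that("every retained draw respects the prior support", {
  rec <- shared_recovery()
  m <- as.matrix(rec$fit)
  pr <- rec$fit$priors
  expect_true(all(m[, "L_inf"] >= 0))
  expect_true(all(m[, "L0"] >= 0))
  expect_true(all(m[, "k"] > pr$k_min & m[, "k"] < pr$k_max))
  expect_true(all(m[, "sigma"] > 0 & m[, "sigma"] < pr$sigma_max))
})

test_that("pointwise log-likelihood rows sum to the joint log-likelihood", {
  rec <- shared_recovery()
  ll <- log_lik_matrix(rec$fit)
  m <- as.matrix(rec$fit)
  expect_equal(ncol(ll), nrow(rec$data))
  for (s in c(1L, 17L, nrow(m))) {
    p <- growth_params(m[s, "L_inf"], m[s, "k"], max(m[s, "L0"], 1e-12), m[s, "sigma"])
    expect_equal(sum(ll[s, ]), log_likelihood("vbgm", p, rec$data), tolerance = 1e-8)
  }
})

test_that("identical seed and settings reproduce identical draws", {
  d <- make_curve_data("vbgm", 100, 0.3, 10, rep(0:15, 2), noise_sd = 5, seed = 9)
  pr <- default_priors(L0_mean = 10, L_inf_mean = 100, sigma_max = 50)
  st <- mcmc_settings(chains = 2, iterations = 1200, warmup = 600, seed = 77)
  f1 <- suppressWarnings(fit_growth_mcmc(d, "vbgm", pr, st))
  f2 <- suppressWarnings(fit_growth_mcmc(d, "vbgm", pr, st))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_growth_mcmc(d, "vbgm", pr,
          mcmc_settings(chains = 2, iterations = 1200, warmup = 600, seed = 78)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("gompertz and logistic fits run under a near-zero L0 prior", {
  # the evaluation floor keeps log(L_inf/L0) finite while the prior pins L0 at 0
  d <- make_curve_data("gompertz", 60, 0.4, 1, rep(0:12, 4), noise_sd = 3, seed = 4)
  pr <- growth_priors(60, 6, 0, 1e-3, 2, 30)
  fit <- suppressWarnings(fit_growth_mcmc(d, "gompertz", pr, quick_settings(seed = 6)))
  expect_true(all(is.finite(as.matrix(fit))))
  expect_lt(summary(fit)$mean[summary(fit)$parameter == "L0"], 1)
})

test_that("settings are validated", {
  expect_error(mcmc_settings(chains = 1), "at least 2 chains")
  expect_error(mcmc_settings(warmup = 10000, iterations = 10000), "warmup")
  expect_error(mcmc_settings(thin = 0), "thin")
})

test_that("thinning keeps every interval-th draw and the log-lik in step", {
  rec <- shared_recovery()
  expect_identical(thin_draws(rec$fit, 1), rec$fit)
  th <- thin_draws(rec$fit, 5)
  expect_equal(nrow(th$draws[[1]]), nrow(rec$fit$draws[[1]]) / 5)
  expect_identical(th$draws[[1]][2, ], rec$fit$draws[[1]][6, ])
  expect_identical(th$log_lik[[2]][3, ], rec$fit$log_lik[[2]][11, ])
  expect_error(thin_draws(rec$fit, 1e6), "fewer than 10")
})

test_that("thinning a persistent chain reduces lag-1 autocorrelation as phi^interval", {
  chains <- lapply(1:2, function(i) {
    cbind(ar1(10000, 0.9, seed = i, mean = 250, sd = 5),
          ar1(10000, 0.9, seed = i + 10, mean = 0.2, sd = 0.02),
          ar1(10000, 0.9, seed = i + 20, mean = 5, sd = 1),
          ar1(10000, 0.9, seed = i + 30, mean = 10, sd = 1))
  })
  fit <- fake_fit(chains)
  before <- autocorrelation_check(fit, max_lag = 5)
  expect_true(all(before$lag1 > 0.8))
  th <- thin_draws(fit, 10)
  expect_equal(nrow(th$draws[[1]]), 1000)
  after <- autocorrelation_check(th, max_lag = 5)
  expect_true(all(after$lag1 < 0.5))  # phi^10 ~ 0.35
})

test_that("posterior growth curves: degeneracy, nesting and coverage", {
  # degenerate draws give a zero-width band equal to the plugged-in curve
  theta <- c(L_inf = 250, k = 0.2, L0 = 0.5, sigma = 10)
  deg <- fake_fit(lapply(1:2, function(i) {
    matrix(rep(theta, each = 200), nrow = 200)
  }))
  curve <- posterior_growth_curve(deg, ages = 0:20, level = 0.95)
  expect_equal(curve$lower, curve$upper, tolerance = 1e-12)
  expect_equal(curve$median,
               predict_length("vbgm", growth_params(250, 0.2, 0.5, 10), 0:20),
               tolerance = 1e-10)

  rec <- shared_recovery()
  b95 <- posterior_growth_curve(rec$fit, ages = 0:29, level = 0.95)
  b50 <- posterior_growth_curve(rec$fit, ages = 0:29, level = 0.5)
  expect_true(all(b50$lower >= b95$lower - 1e-9))
  expect_true(all(b50$upper <= b95$upper + 1e-9))
  expect_true(all(b95$lower <= b95$median & b95$median <= b95$upper))
  truth <- predict_length("vbgm", growth_params(250, 0.2, 1e-6, 10), 0:29)
  inside <- truth >= b95$lower & truth <= b95$upper
  expect_gte(mean(inside), 0.9)
  expect_error(posterior_growth_curve(rec$fit, ages = 0:5, level = 1.2), "level")
})

test_that("fit summaries and serialisation carry the expected structure", {
  rec <- shared_recovery()
  sm <- summary(rec$fit)
  expect_setequal(sm$parameter, c("L_inf", "k", "L0", "sigma"))
  expect_true(all(sm$q2.5 <= sm$median & sm$median <= sm$q97.5))
  expect_true(all(sm$rhat >= 1 - 1e-3))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(rec$fit, csv)
  tab <- read.csv(csv)
  expect_equal(names(tab), c("chain", "iteration", "L_inf", "k", "L0", "sigma"))
  expect_equal(nrow(tab), sum(vapply(rec$fit$draws, nrow, integer(1))))
  expect_equal(tab$L_inf[1], unname(rec$fit$draws[[1]][1, "L_inf"]),
               tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_fit_json(rec$fit, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$method, "mcmc")
  expect_equal(parsed$settings$seed, rec$fit$settings$seed)
})
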