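# Selectivity functions, survivorship, the multinomial age-sampling process
# and the multiplicative-error length generator.

test_that("selectivity functions hit their closed-form values", {
  inc <- scenario_preset("increasing")  # logistic, slope 0.7, a50 12
  expect_equal(selectivity_at_age(inc, 12), 0.5, tolerance = 1e-12)
  expect_equal(selectivity_at_age(inc, 0), 1 / (1 + exp(8.4)), tolerance = 1e-12)
  expect_equal(selectivity_at_age(inc, 0), 2.248e-4, tolerance = 1e-3)
  dome <- scenario_preset("dome")       # Gaussian, mean 10, sd 2
  expect_equal(selectivity_at_age(dome, 10), 1)
  expect_equal(selectivity_at_age(dome, 12), exp(-0.5), tolerance = 1e-12)
  unif <- scenario_preset("uniform")
  expect_equal(selectivity_at_age(unif, c(0, 7, 30)), rep(1, 3))
  expect_error(selectivity_at_age(inc, 31), "max_age")
})

test_that("increasing and decreasing logistic forms with equal shape sum to one", {
  inc <- selectivity_scenario("logistic_increasing", slope = 0.7, a50 = 12)
  dec <- selectivity_scenario("logistic_decreasing", slope = 0.7, a50 = 12)
  ages <- seq(0, 30, by = 0.25)
  expect_equal(selectivity_at_age(inc, ages) + selectivity_at_age(dec, ages),
               rep(1, length(ages)), tolerance = 1e-12)
})

test_that("survivorship decays exponentially from one", {
  l <- survivorship(M = 0.2, max_age = 30)
  expect_equal(l[1], 1)
  expect_equal(l[6], exp(-1), tolerance = 1e-12)   # age 5
  expect_equal(l[6], 0.3679, tolerance = 1e-4)
  ratios <- l[-1] / l[-length(l)]
  expect_equal(ratios, rep(exp(-0.2), 30), tolerance = 1e-12)
  expect_true(all(diff(l) < 0))
  expect_error(survivorship(0, 30), "M must be")
})

test_that("sampling probabilities combine survivorship and selectivity", {
  unif <- scenario_preset("uniform")
  p <- sampling_probabilities(unif)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, exp(-0.2 * (0:30)) / sum(exp(-0.2 * (0:30))), tolerance = 1e-12)
  inc <- scenario_preset("increasing")
  p_inc <- sampling_probabilities(inc)
  expect_equal(sum(p_inc), 1, tolerance = 1e-12)
  modal_age <- which.max(p_inc) - 1L
  expect_true(modal_age >= 10 && modal_age <= 16)
})

test_that("the generator is exact at zero noise and reproducible under a seed", {
  dome <- scenario_preset("dome")
  sim0 <- simulate_lengths(list(L_inf = 250, k = 0.2, L0 = 0, sigma_mult = 0),
                           dome, n = 150, seed = 5)
  expect_equal(sim0$data$length,
               250 * (1 - exp(-0.2 * sim0$data$age)), tolerance = 1e-12)
  s1 <- simulate_lengths(scenario = dome, n = 150, seed = 12)
  s2 <- simulate_lengths(scenario = dome, n = 150, seed = 12)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_lengths(scenario = dome, n = 150, seed = 13)
  expect_false(identical(s1$data, s3$data))
})

test_that("simulated records respect the declared support", {
  inc <- scenario_preset("increasing")
  sim <- simulate_lengths(scenario = inc, n = 2000, seed = 3)
  expect_true(all(sim$data$age == floor(sim$data$age)))
  expect_true(all(sim$data$age >= 0 & sim$data$age <= 30))
  # with L0 = 0, age-0 records are exactly zero and all others positive
  dec <- scenario_preset("decreasing")
  sim2 <- simulate_lengths(scenario = dec, n = 2000, seed = 4)
  zero_age <- sim2$data$age == 0
  expect_true(all(sim2$data$length[zero_age] == 0))
  expect_true(all(sim2$data$length[!zero_age] > 0))
})

test_that("empirical age frequencies match the sampling distribution", {
  dome <- scenario_preset("dome")
  sim <- simulate_lengths(scenario = dome, n = 20000, seed = 9)
  p <- sampling_probabilities(dome)
  counts <- tabulate(sim$data$age + 1L, nbins = 31)
  keep <- p * 20000 >= 5  # pool nothing, just drop the vanishing cells
  gof <- suppressWarnings(chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("length variability converges to the multiplicative CV", {
  unif <- scenario_preset("uniform")
  sim <- simulate_lengths(list(L_inf = 250, k = 0.2, L0 = 30, sigma_mult = 0.1),
                          unif, n = 30000, seed = 21)
  by_age <- split(sim$data$length, sim$data$age)
  rich <- by_age[vapply(by_age, length, integer(1)) >= 500]
  cvs <- vapply(rich, function(x) sd(x) / mean(x), numeric(1))
  expect_true(all(abs(cvs - 0.1) <= 0.01))
})

test_that("scenario construction validates its fields", {
  expect_error(selectivity_scenario("logistic_increasing", slope = 0.7), "a50")
  expect_error(selectivity_scenario("logistic_increasing", slope = -1, a50 = 5), "slope")
  expect_error(selectivity_scenario("dome", dome_mean = 10, dome_sd = 0), "dome_sd")
  expect_error(selectivity_scenario("uniform", M = -0.2), "M must be")
  expect_error(simulate_lengths(scenario = scenario_preset("dome"), n = 0, seed = 1),
               "n must be")
  expect_error(simulate_lengths(list(L_inf = 250, k = 0.2, L0 = 0, sigma_mult = 0.5),
                                scenario_preset("dome"), n = 10, seed = 1,
                                kind = "gompertz"), "requires L0")
})
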