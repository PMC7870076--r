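# Gear-selectivity sampling simulator. Length-at-age data are drawn from a
# growth curve with a multiplicative error structure (SD proportional to mean
# length, emulating the increase of individual growth variation with age),
# while ages are drawn from a multinomial over integer ages with probability
# proportional to survivorship (exponential decay at natural mortality M)
# times gear selectivity at age. This is the substrate for every
# parameter-recovery experiment in the package.

#' Selectivity scenario
#'
#' Describes the sampling process of a simulated ageing study: which ages the
#' gear can catch (`form`) and how many fish of each age remain alive to be
#' caught (natural mortality `M`).
#'
#' @param form One of `"logistic_increasing"` (gear targets older fish),
#'   `"logistic_decreasing"` (targets juveniles), `"dome"` (targets a central
#'   age band) or `"uniform"` (all ages equally catchable).
#' @param slope Steepness (1/yr) of the logistic forms.
#' @param a50 Age at 50% selectivity (years) of the logistic forms.
#' @param dome_mean,dome_sd Mean and SD (years) of the Gaussian dome, scaled
#'   to peak at 1 (the scaling is inconsequential after normalisation but is
#'   fixed for reproducibility).
#' @param M Instantaneous natural mortality (1/yr, default 0.2).
#' @param max_age Oldest age (years, integer) in the simulated population
#'   (default 30, by which survivorship at M = 0.2 has fallen to ~0.25%).
#' @return An object of class `selectivity_scenario`.
#' @seealso [scenario_preset()] for the three standard configurations.
#' @export
selectivity_scenario <- function(form = c("logistic_increasing", "logistic_decreasing",
                                          "dome", "uniform"),
                                 slope = NULL, a50 = NULL,
                                 dome_mean = NULL, dome_sd = NULL,
                                 M = 0.2, max_age = 30) {
  form <- match.arg(form)
  max_age <- as.integer(max_age)
  if (M <= 0) stop("M must be > 0", call. = FALSE)
  if (max_age < 1L) stop("max_age must be >= 1", call. = FALSE)
  if (form %in% c("logistic_increasing", "logistic_decreasing")) {
    if (is.null(slope) || is.null(a50)) {
      stop("logistic selectivity needs `slope` and `a50`", call. = FALSE)
    }
    if (slope <= 0) stop("slope must be > 0", call. = FALSE)
    if (a50 <= 0 || a50 >= max_age) stop("need 0 < a50 < max_age", call. = FALSE)
  }
  if (form == "dome") {
    if (is.null(dome_mean) || is.null(dome_sd)) {
      stop("dome selectivity needs `dome_mean` and `dome_sd`", call. = FALSE)
    }
    if (dome_sd <= 0) stop("dome_sd must be > 0", call. = FALSE)
  }
  structure(list(form = form, slope = slope, a50 = a50,
                 dome_mean = dome_mean, dome_sd = dome_sd,
                 M = M, max_age = max_age),
            class = "selectivity_scenario")
}

#' Standard selectivity scenario presets
#'
#' The three configurations used in the selectivity recovery experiments:
#' `"increasing"` (logistic, slope 0.7, a50 12 yr — juveniles unsampled),
#' `"decreasing"` (logistic, slope 1, a50 1.5 yr — old fish unsampled) and
#' `"dome"` (Gaussian, mean 10 yr, SD 2 yr). All use M = 0.2 and max age 30.
#'
#' @param name One of `"increasing"`, `"decreasing"`, `"dome"`, `"uniform"`.
#' @return A [selectivity_scenario()].
#' @export
scenario_preset <- function(name = c("increasing", "decreasing", "dome", "uniform")) {
  name <- match.arg(name)
  switch(name,
    increasing = selectivity_scenario("logistic_increasing", slope = 0.7, a50 = 12),
    decreasing = selectivity_scenario("logistic_decreasing", slope = 1, a50 = 1.5),
    dome = selectivity_scenario("dome", dome_mean = 10, dome_sd = 2),
    uniform = selectivity_scenario("uniform"))
}

#' @export
print.selectivity_scenario <- function(x, ...) {
  desc <- switch(x$form,
    logistic_increasing = sprintf("logistic increasing (slope %g, a50 %g yr)", x$slope, x$a50),
    logistic_decreasing = sprintf("logistic decreasing (slope %g, a50 %g yr)", x$slope, x$a50),
    dome = sprintf("dome (mean %g yr, SD %g yr)", x$dome_mean, x$dome_sd),
    uniform = "uniform")
  cat(sprintf("Selectivity scenario: %s; M = %g /yr, max age %d yr\n",
              desc, x$M, x$max_age))
  invisible(x)
}

#' Selectivity at age
#'
#' Relative catchability of an individual of the given age:
#' `1 / (1 + exp(-slope * (a - a50)))` for the increasing logistic form, its
#' mirror image for the decreasing form, a Gaussian in age scaled to peak 1
#' for the dome, and 1 for uniform selectivity.
#'
#' @param scenario A [selectivity_scenario()].
#' @param age Numeric vector of ages in `[0, max_age]`.
#' @return Selectivity values in (0, 1].
#' @export
selectivity_at_age <- function(scenario, age) {
  stopifnot(inherits(scenario, "selectivity_scenario"))
  if (any(age < 0 | age > scenario$max_age)) {
    stop("age must lie in [0, max_age]", call. = FALSE)
  }
  switch(scenario$form,
    logistic_increasing = 1 / (1 + exp(-scenario$slope * (age - scenario$a50))),
    logistic_decreasing = 1 / (1 + exp(scenario$slope * (age - scenario$a50))),
    dome = exp(-0.5 * ((age - scenario$dome_mean) / scenario$dome_sd)^2),
    uniform = rep(1, length(age)))
}

#' Survivorship to age
#'
#' Fraction of a cohort alive at each integer age under constant natural
#' mortality: `l_0 = 1`, `l_a = l_(a-1) * exp(-M)`.
#'
#' @param M Natural mortality (1/yr, > 0).
#' @param max_age Oldest age (years).
#' @return Numeric vector of length `max_age + 1` for ages `0:max_age`.
#' @export
survivorship <- function(M, max_age) {
  if (M <= 0) stop("M must be > 0", call. = FALSE)
  exp(-M * (0:max_age))
}

#' Age-sampling probabilities of a scenario
#'
#' The probability of sampling an individual of each integer age
#' `0:max_age`, proportional to survivorship times selectivity and
#' normalised to sum to 1 (the multinomial observation process).
#'
#' @param scenario A [selectivity_scenario()].
#' @return Numeric probability vector over ages `0:max_age`.
#' @export
sampling_probabilities <- function(scenario) {
  stopifnot(inherits(scenario, "selectivity_scenario"))
  ages <- 0:scenario$max_age
  w <- survivorship(scenario$M, scenario$max_age) * selectivity_at_age(scenario, ages)
  if (all(w <= 0) || !any(is.finite(w) & w > 0)) {
    stop("all survivorship x selectivity products are zero", call. = FALSE)
  }
  w / sum(w)
}

#' Simulate a selectivity-biased length-at-age sample
#'
#' Draws `n` integer ages from [sampling_probabilities()] and then lengths
#' from `N(mean_a, mean_a * sigma_mult)`, where `mean_a` is the growth-curve
#' length at age `a` — the multiplicative error structure under which the SD
#' of length grows in proportion to its mean. Negative length draws are
#' redrawn. When `L0 = 0`, age-0 records have mean and SD zero and are
#' emitted as exact zeros. One root seed is split into independent streams
#' for the age sampling and the length noise, so the two stages are
#' individually reproducible.
#'
#' @param true Named list or vector with `L_inf`, `k`, `L0` (cm, cm, and
#'   1/yr) and `sigma_mult` (unitless CV of length at age). Defaults to the
#'   standard recovery-experiment truth: `L_inf = 250`, `k = 0.2`, `L0 = 0`,
#'   `sigma_mult = 0.5`.
#' @param scenario A [selectivity_scenario()].
#' @param n Sample size (>= 1).
#' @param seed Integer root seed.
#' @param kind Growth curve generating the mean lengths (default `"vbgm"`).
#' @return An object of class `growth_sim`: list with `data`
#'   (a [growth_data()]), `true`, `scenario`, `seed`, `kind`.
#' @examples
#' sim <- simulate_lengths(scenario = scenario_preset("dome"), n = 100, seed = 1)
#' head(sim$data)
#' @export
simulate_lengths <- function(true = list(L_inf = 250, k = 0.2, L0 = 0, sigma_mult = 0.5),
                             scenario, n, seed = 1, kind = "vbgm") {
  kind <- match_kind(kind)
  stopifnot(inherits(scenario, "selectivity_scenario"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  true <- as.list(true)
  needed <- c("L_inf", "k", "L0", "sigma_mult")
  if (!all(needed %in% names(true))) {
    stop("`true` must provide L_inf, k, L0 and sigma_mult", call. = FALSE)
  }
  if (true$sigma_mult < 0) stop("sigma_mult must be >= 0", call. = FALSE)
  if (kind != "vbgm" && true$L0 < L0_FLOOR) {
    stop(sprintf("the %s generating curve requires L0 >= %g", kind, L0_FLOOR),
         call. = FALSE)
  }

  probs <- sampling_probabilities(scenario)
  seed <- as.integer(seed)
  seed_age <- seed
  seed_noise <- (seed + 1000003L) %% .Machine$integer.max

  set.seed(seed_age)
  ages <- sample(0:scenario$max_age, n, replace = TRUE, prob = probs)
  mean_len <- predict_length_core(kind, true$L_inf, true$k, true$L0, ages)
  sd_len <- mean_len * true$sigma_mult

  set.seed(seed_noise)
  lengths <- stats::rnorm(n, mean_len, sd_len)
  # redraw (rather than truncate) negative lengths; impossible where sd = 0
  repeat {
    bad <- which(lengths < 0)
    if (!length(bad)) break
    lengths[bad] <- stats::rnorm(length(bad), mean_len[bad], sd_len[bad])
  }

  structure(list(data = growth_data(ages, lengths),
                 true = true[needed], scenario = scenario,
                 seed = seed, kind = kind),
            class = "growth_sim")
}

#' @export
print.growth_sim <- function(x, ...) {
  cat(sprintf("Simulated %s length-at-age sample: n = %d, seed = %d\n",
              x$kind, nrow(x$data), x$seed))
  cat(sprintf("  truth: L_inf = %g, k = %g, L0 = %g, sigma_mult = %g\n",
              x$true$L_inf, x$true$k, x$true$L0, x$true$sigma_mult))
  print(x$scenario)
  invisible(x)
}
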