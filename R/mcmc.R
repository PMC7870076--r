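# Bayesian estimation of any candidate growth model. The posterior is
# proportional to the normal-residual likelihood times the shared prior set;
# sampling is delegated to JAGS (via rjags) with one deterministically seeded
# RNG per chain, so identical settings reproduce identical draws. The model
# is specified here; JAGS supplies only the MCMC kernel.

PARAM_NAMES <- c("L_inf", "k", "L0", "sigma")

#' MCMC sampler settings
#'
#' @param chains Number of chains (>= 2; default 4).
#' @param iterations Total iterations per chain, warmup included
#'   (default 10000).
#' @param warmup Warmup (burn-in) iterations discarded from the start of each
#'   chain (default 5000). Sampler adaptation happens inside this budget.
#' @param thin Keep every `thin`-th post-warmup draw (default 1).
#' @param seed Integer seed controlling chain RNGs and initial values.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, iterations = 10000, warmup = 5000,
                          thin = 1, seed = 1) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  warmup <- as.integer(warmup); thin <- as.integer(thin); seed <- as.integer(seed)
  if (chains < 2L) stop("need at least 2 chains", call. = FALSE)
  if (warmup >= iterations) stop("warmup must be smaller than iterations", call. = FALSE)
  if (warmup < 0L) stop("warmup must be >= 0", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, seed = seed), class = "mcmc_settings")
}

# JAGS model code for one candidate model. Hyperparameters enter through the
# data list, so the same code serves any prior set. The L0 floor mirrors the
# evaluation floor of the R-side curves.
jags_model_code <- function(kind) {
  mu_expr <- switch(kind,
    vbgm = "L_inf - (L_inf - L0) * exp(-k * age[i])",
    gompertz = "L0c * exp(log(L_inf / L0c) * (1 - exp(-k * age[i])))",
    logistic = "(L_inf * L0c * exp(k * age[i])) / (L_inf + L0c * (exp(k * age[i]) - 1))")
  clamp <- if (kind == "vbgm") "" else "  L0c <- max(L0, 1.0E-6)\n"
  paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    mu[i] <- ", mu_expr, "\n",
    "    y[i] ~ dnorm(mu[i], tau)\n",
    "  }\n",
    clamp,
    "  L_inf ~ dnorm(L_inf_mean, 1 / (L_inf_sd * L_inf_sd)) T(0,)\n",
    "  L0 ~ dnorm(L0_mean, 1 / (L0_sd * L0_sd)) T(0,)\n",
    "  k ~ dunif(k_min, k_max)\n",
    "  sigma ~ dunif(0, sigma_max)\n",
    "  tau <- 1 / (sigma * sigma)\n",
    "}\n")
}

# Initial values: k and sigma start at the midpoints of their uniform
# supports, L_inf and L0 are drawn from their (truncated) priors; each chain
# gets an independent jitter and its own RNG seed so runs are reproducible.
make_inits <- function(priors, settings) {
  set.seed(settings$seed)
  lapply(seq_len(settings$chains), function(ch) {
    jit <- function(x, lo, hi) min(max(x * stats::runif(1, 0.85, 1.15), lo), hi)
    k_mid <- (priors$k_min + priors$k_max) / 2
    s_mid <- priors$sigma_max / 2
    list(
      L_inf = rtruncnorm_lower(1, priors$L_inf_mean, priors$L_inf_sd),
      L0 = rtruncnorm_lower(1, priors$L0_mean, priors$L0_sd),
      k = jit(k_mid, priors$k_min + 1e-9, priors$k_max - 1e-9),
      sigma = jit(s_mid, 1e-9, priors$sigma_max - 1e-9),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = settings$seed + ch
    )
  })
}

#' Fit a growth model by MCMC
#'
#' Samples the posterior of (`L_inf`, `k`, `L0`, `sigma`) for one candidate
#' model under the shared prior scheme, records the pointwise log-likelihood
#' of every retained draw (needed for LOOIC), and computes split-Rhat and
#' effective sample sizes. A warning (not an error) is issued when any
#' split-Rhat exceeds `rhat_threshold`.
#'
#' @param data A [growth_data()] dataset (or data frame with `age`, `length`).
#' @param kind Growth model name, see [growth_model_kinds()].
#' @param priors A [growth_priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @param rhat_threshold Convergence reporting threshold (default 1.01).
#' @return An object of class `growth_mcmc_fit` with elements `kind`,
#'   `draws` (per-chain matrices with columns `L_inf`, `k`, `L0`, `sigma`),
#'   `log_lik` (per-chain draws-by-observation matrices), `data`, `priors`,
#'   `settings`, `rhat`, `ess`.
#' @examples
#' \donttest{
#' d <- growth_data(age = rep(0:15, 4), length = predict_length(
#'   "vbgm", growth_params(100, 0.3, 10, 5), rep(0:15, 4)) + rnorm(64, 0, 5))
#' pr <- default_priors(L0_mean = 10, L_inf_mean = 100)
#' fit <- fit_growth_mcmc(d, "vbgm", pr, mcmc_settings(2, 2000, 1000, seed = 1))
#' summary(fit)
#' }
#' @export
fit_growth_mcmc <- function(data, kind, priors, settings = mcmc_settings(),
                            rhat_threshold = 1.01) {
  kind <- match_kind(kind)
  data <- as_growth_data(data)
  stopifnot(inherits(priors, "growth_priors"), inherits(settings, "mcmc_settings"))

  jags_data <- list(n = nrow(data), age = data$age, y = data$length,
                    L_inf_mean = priors$L_inf_mean, L_inf_sd = priors$L_inf_sd,
                    L0_mean = priors$L0_mean, L0_sd = priors$L0_sd,
                    k_min = priors$k_min, k_max = priors$k_max,
                    sigma_max = priors$sigma_max)
  n_adapt <- min(1000L, settings$warmup)
  model <- tryCatch(
    rjags::jags.model(textConnection(jags_model_code(kind)), data = jags_data,
                      inits = make_inits(priors, settings),
                      n.chains = settings$chains, n.adapt = n_adapt,
                      quiet = TRUE),
    error = function(e) stop(sprintf("MCMC sampler failed to initialise for %s: %s",
                                     kind, conditionMessage(e)), call. = FALSE))
  if (settings$warmup > n_adapt) {
    stats::update(model, n.iter = settings$warmup - n_adapt, progress.bar = "none")
  }
  retained_iter <- settings$iterations - settings$warmup
  samp <- tryCatch(
    rjags::coda.samples(model, variable.names = PARAM_NAMES,
                        n.iter = retained_iter, thin = settings$thin,
                        progress.bar = "none"),
    error = function(e) stop(sprintf("MCMC sampling failed for %s: %s",
                                     kind, conditionMessage(e)), call. = FALSE))

  draws <- lapply(samp, function(ch) {
    m <- as.matrix(ch)[, PARAM_NAMES, drop = FALSE]
    if (any(!is.finite(m))) {
      stop(sprintf("MCMC sampler produced non-finite draws for %s", kind),
           call. = FALSE)
    }
    m
  })
  log_lik <- lapply(draws, function(m) pointwise_log_lik(kind, m, data))

  fit <- structure(list(kind = kind, draws = draws, log_lik = log_lik,
                        data = data, priors = priors, settings = settings,
                        rhat = NULL, ess = NULL),
                   class = "growth_mcmc_fit")
  fit$rhat <- gelman_rubin(fit)
  fit$ess <- effective_size(fit)
  bad <- fit$rhat[is.finite(fit$rhat) & fit$rhat > rhat_threshold]
  if (length(bad)) {
    warning(sprintf("convergence not reached for %s: split-Rhat > %.3f for %s",
                    kind, rhat_threshold, paste(names(bad), collapse = ", ")),
            call. = FALSE)
  }
  fit
}

#' Pooled posterior draws as a matrix
#'
#' @param x A `growth_mcmc_fit`.
#' @param ... Unused.
#' @return Matrix with all chains stacked, columns `L_inf`, `k`, `L0`, `sigma`.
#' @export
as.matrix.growth_mcmc_fit <- function(x, ...) do.call(rbind, x$draws)

# Stacked pointwise log-likelihood (total retained draws x n observations).
#' Pointwise log-likelihood matrix of a fit
#'
#' @param fit A `growth_mcmc_fit`.
#' @return Matrix (retained draws x observations) of log densities.
#' @export
log_lik_matrix <- function(fit) {
  stopifnot(inherits(fit, "growth_mcmc_fit"))
  do.call(rbind, fit$log_lik)
}

#' Thin retained posterior draws
#'
#' Keeps every `interval`-th retained draw of every chain; the pointwise
#' log-likelihood is thinned identically. Thinning trades draws for reduced
#' autocorrelation and is only worthwhile when [autocorrelation_check()]
#' flags a parameter.
#'
#' @param fit A `growth_mcmc_fit`.
#' @param interval Positive integer; `interval = 1` returns the fit unchanged.
#' @return A `growth_mcmc_fit` with thinned draws.
#' @export
thin_draws <- function(fit, interval) {
  stopifnot(inherits(fit, "growth_mcmc_fit"))
  interval <- as.integer(interval)
  if (interval < 1L) stop("interval must be >= 1", call. = FALSE)
  if (interval == 1L) return(fit)
  keep <- lapply(fit$draws, function(m) seq(1L, nrow(m), by = interval))
  if (sum(lengths(keep)) < 10L) {
    stop("thinning would leave fewer than 10 draws", call. = FALSE)
  }
  fit$draws <- Map(function(m, idx) m[idx, , drop = FALSE], fit$draws, keep)
  fit$log_lik <- Map(function(m, idx) m[idx, , drop = FALSE], fit$log_lik, keep)
  fit$settings$thin <- fit$settings$thin * interval
  fit$rhat <- gelman_rubin(fit)
  fit$ess <- effective_size(fit)
  fit
}

#' Posterior summary of a growth MCMC fit
#'
#' @param object A `growth_mcmc_fit`.
#' @param ... Unused.
#' @return Data frame with one row per parameter: posterior mean, SD, median,
#'   2.5% and 97.5% quantiles, split-Rhat and effective sample size.
#' @export
summary.growth_mcmc_fit <- function(object, ...) {
  m <- as.matrix(object)
  q <- t(apply(m, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2, stats::sd),
                    median = q[, 1], q2.5 = q[, 2], q97.5 = q[, 3],
                    rhat = object$rhat[colnames(m)],
                    ess = object$ess[colnames(m)],
                    row.names = NULL)
  class(out) <- c("growth_fit_summary", "data.frame")
  out
}

#' @export
print.growth_mcmc_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s growth fit: %d chains x %d retained draws (n = %d)\n",
              x$kind, length(x$draws), nrow(x$draws[[1]]), nrow(x$data)))
  print(as.data.frame(summary(x)), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Posterior growth curve with credibility band
#'
#' For each age on a grid, computes the posterior median predicted length and
#' a central credibility interval across all retained draws. These bands are
#' the Bayesian analogue of bootstrapped confidence intervals around a
#' frequentist growth curve.
#'
#' @param fit A `growth_mcmc_fit`.
#' @param ages Numeric age grid (default: 100 points spanning the observed
#'   age range from 0).
#' @param level Credibility level in (0, 1) (default 0.95).
#' @return Data frame with columns `age`, `median`, `lower`, `upper`.
#' @export
posterior_growth_curve <- function(fit, ages = NULL, level = 0.95) {
  stopifnot(inherits(fit, "growth_mcmc_fit"))
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  if (is.null(ages)) ages <- seq(0, max(fit$data$age), length.out = 100L)
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)
  m <- as.matrix(fit)
  L_inf <- m[, "L_inf"]; k <- m[, "k"]
  L0 <- pmax(m[, "L0"], if (fit$kind == "vbgm") 0 else L0_FLOOR)
  probs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  out <- vapply(ages, function(a) {
    pred <- switch(fit$kind,
      vbgm = L_inf - (L_inf - L0) * exp(-k * a),
      gompertz = L0 * exp(log(L_inf / L0) * (1 - exp(-k * a))),
      logistic = (L_inf * L0 * exp(k * a)) / (L_inf + L0 * (exp(k * a) - 1)))
    stats::quantile(pred, probs, names = FALSE)
  }, numeric(3))
  data.frame(age = ages, median = out[1, ], lower = out[2, ], upper = out[3, ])
}

#' Write retained draws to CSV
#'
#' One row per retained draw with columns `chain`, `iteration`, `L_inf`, `k`,
#' `L0`, `sigma`.
#'
#' @param fit A `growth_mcmc_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "growth_mcmc_fit"))
  tabs <- Map(function(m, ch) {
    data.frame(chain = ch, iteration = seq_len(nrow(m)), m)
  }, fit$draws, seq_along(fit$draws))
  tab <- do.call(rbind, tabs)
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON fit summary
#'
#' Serialises posterior summaries (or NLS estimates), settings and priors to
#' a JSON file; the `method` field (`"mcmc"` or `"nls"`) lets comparison
#' reports interleave both arms.
#'
#' @param fit A `growth_mcmc_fit` or `growth_nls_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (inherits(fit, "growth_mcmc_fit")) {
    payload <- list(
      method = "mcmc", model = fit$kind,
      n = nrow(fit$data),
      summary = summary(fit),
      settings = unclass(fit$settings),
      priors = unclass(fit$priors))
  } else if (inherits(fit, "growth_nls_fit")) {
    payload <- list(
      method = "nls", model = fit$kind,
      n = fit$n, converged = fit$converged,
      estimates = as.list(fit$estimates),
      se = as.list(fit$se),
      sigma2 = fit$sigma2,
      fixed_L0 = if (is.null(fit$fixed_L0)) NULL else fit$fixed_L0)
  } else {
    stop("`fit` must be a growth_mcmc_fit or growth_nls_fit", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
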