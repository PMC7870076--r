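# Frequentist comparator arm: nonlinear least squares (Levenberg-Marquardt)
# with free or fixed length-at-birth, asymptotic standard errors from the
# curvature at the optimum, the ML residual variance RSS/n feeding AIC, and
# nonparametric case-resampling bootstrap bands around the fitted curve.

nls_formula <- function(kind, fixed_L0 = NULL) {
  rhs <- switch(kind,
    vbgm = "L_inf - (L_inf - L0) * exp(-k * age)",
    gompertz = "L0 * exp(log(L_inf / L0) * (1 - exp(-k * age)))",
    logistic = "(L_inf * L0 * exp(k * age)) / (L_inf + L0 * (exp(k * age) - 1))")
  if (!is.null(fixed_L0)) {
    rhs <- gsub("\\bL0\\b", format(fixed_L0, digits = 17), rhs)
  }
  stats::as.formula(paste("length ~", rhs))
}

# Scale-free default starting values; the optimiser is restarted from
# jittered versions of these before declaring non-convergence.
nls_default_start <- function(data, kind, fixed_L0) {
  start <- list(L_inf = 1.1 * max(data$length),
                L0 = max(min(data$length) / 2, 1e-3),
                k = 0.1)
  if (!is.null(fixed_L0)) start$L0 <- NULL
  start
}

nls_bounds <- function(kind, fixed_L0) {
  lower <- c(L_inf = 1e-6, L0 = if (kind == "vbgm") 0 else L0_FLOOR, k = 1e-5)
  if (!is.null(fixed_L0)) lower <- lower[c("L_inf", "k")]
  lower
}

try_nlsLM <- function(data, kind, start, fixed_L0) {
  lower <- nls_bounds(kind, fixed_L0)
  start <- start[names(lower)]
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      nls_formula(kind, fixed_L0), data = data, start = start,
      lower = unname(lower),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) e)
}

#' Fit a growth model by nonlinear least squares
#'
#' Minimises the residual sum of squares of observed length against
#' [predict_length()] using Levenberg-Marquardt, optionally with
#' length-at-birth fixed at a known value. Reports point estimates,
#' asymptotic standard errors, and the ML residual variance
#' `sigma2 = RSS / n` used by [aic()]. Non-convergence is reported through
#' the `converged` flag and `message`, never as an error, so that
#' "did not converge" outcomes can be tabulated.
#'
#' @param data A [growth_data()] dataset.
#' @param kind Growth model name, see [growth_model_kinds()].
#' @param start Optional [growth_params()] (or named list) of starting
#'   values; defaults are scale-free functions of the data.
#' @param fixed_L0 Optional fixed length-at-birth (cm). Must be strictly
#'   positive for the Gompertz and logistic curves.
#' @param n_restarts Jittered restarts attempted on failure (default 5).
#' @return An object of class `growth_nls_fit` with `estimates` (named
#'   vector `L_inf`, `k`, `L0`, `sigma`, where `sigma = sqrt(sigma2)`;
#'   pathological estimates such as `L0 > L_inf` are reported as found,
#'   since exposing them is the point of the comparator arm), `se`, `sigma2`,
#'   `n`, `n_free_params`, `converged`, `message`, `fixed_L0`, `data`.
#' @export
fit_growth_nls <- function(data, kind, start = NULL, fixed_L0 = NULL,
                           n_restarts = 5) {
  kind <- match_kind(kind)
  data <- as_growth_data(data)
  if (!is.null(fixed_L0)) {
    if (kind != "vbgm" && fixed_L0 < L0_FLOOR) {
      stop(sprintf("fixed L0 = %g is invalid for the %s curve (its equation involves log/ratio of L0)",
                   fixed_L0, kind), call. = FALSE)
    }
    if (fixed_L0 < 0) stop("fixed_L0 must be >= 0", call. = FALSE)
  }
  n_free <- if (is.null(fixed_L0)) 3L else 2L
  if (nrow(data) <= n_free) {
    stop(sprintf("need more than %d observations to fit %d free parameters",
                 n_free, n_free), call. = FALSE)
  }
  s0 <- nls_default_start(data, kind, fixed_L0)
  if (!is.null(start)) {
    start <- if (inherits(start, "growth_params")) unclass(start) else as.list(start)
    for (nm in intersect(names(start), names(s0))) s0[[nm]] <- start[[nm]]
  }

  fit <- try_nlsLM(data, kind, s0, fixed_L0)
  if (inherits(fit, "error")) {
    attempt <- 0L
    set.seed(sum(utf8ToInt(kind)) + nrow(data))  # deterministic restart jitter
    while (inherits(fit, "error") && attempt < n_restarts) {
      attempt <- attempt + 1L
      s_j <- lapply(s0, function(v) v * stats::runif(1, 0.5, 1.5))
      fit <- try_nlsLM(data, kind, s_j, fixed_L0)
    }
  }

  if (inherits(fit, "error")) {
    return(structure(list(kind = kind, estimates = NULL, se = NULL,
                          sigma2 = NA_real_, n = nrow(data),
                          n_free_params = n_free, converged = FALSE,
                          message = paste("did not converge:", conditionMessage(fit)),
                          fixed_L0 = fixed_L0, data = data),
                     class = "growth_nls_fit"))
  }

  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  L0_hat <- if (is.null(fixed_L0)) est[["L0"]] else fixed_L0
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / nrow(data)
  estimates <- c(L_inf = est[["L_inf"]], k = est[["k"]], L0 = L0_hat,
                 sigma = sqrt(sigma2))
  se_out <- c(L_inf = se[["L_inf"]], k = se[["k"]],
              L0 = if (is.null(fixed_L0)) se[["L0"]] else NA_real_,
              sigma = NA_real_)
  structure(list(kind = kind, estimates = estimates, se = se_out,
                 sigma2 = sigma2, n = nrow(data), n_free_params = n_free,
                 converged = TRUE, message = "converged",
                 fixed_L0 = fixed_L0, data = data),
            class = "growth_nls_fit")
}

#' @export
print.growth_nls_fit <- function(x, ...) {
  cat(sprintf("NLS %s growth fit (n = %d)%s\n", x$kind, x$n,
              if (is.null(x$fixed_L0)) "" else sprintf(", L0 fixed at %g", x$fixed_L0)))
  if (!x$converged) {
    cat(" ", x$message, "\n")
  } else {
    tab <- data.frame(estimate = x$estimates, se = x$se)
    print(tab, digits = 4)
    cat(sprintf("  residual variance (RSS/n): %.4g\n", x$sigma2))
  }
  invisible(x)
}

#' Bootstrap confidence band around an NLS growth curve
#'
#' Nonparametric case resampling: records are resampled with replacement,
#' the model is refitted to each replicate, and per-age percentile bounds of
#' the replicate curves form the band. Replicates whose refits fail are
#' dropped and counted; more than 50% failures is an error.
#'
#' @inheritParams fit_growth_nls
#' @param replicates Number of bootstrap replicates (>= 200; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @param ages Age grid for the band (default 100 points over the observed
#'   range from 0).
#' @return List of class `bootstrap_band` with a data frame `band`
#'   (`age`, `lower`, `upper`), `replicates`, `failed`, `level`, `seed`.
#' @export
bootstrap_band <- function(data, kind, replicates = 1000, level = 0.95,
                           seed = 1, ages = NULL, fixed_L0 = NULL) {
  kind <- match_kind(kind)
  data <- as_growth_data(data)
  if (replicates < 200) stop("use at least 200 bootstrap replicates", call. = FALSE)
  if (is.null(ages)) ages <- seq(0, max(data$age), length.out = 100L)
  set.seed(seed)
  idx <- matrix(sample.int(nrow(data), nrow(data) * replicates, replace = TRUE),
                nrow = replicates)
  curves <- matrix(NA_real_, replicates, length(ages))
  failed <- 0L
  for (r in seq_len(replicates)) {
    d_r <- data[idx[r, ], , drop = FALSE]
    f <- fit_growth_nls(d_r, kind, fixed_L0 = fixed_L0, n_restarts = 1)
    if (!f$converged) { failed <- failed + 1L; next }
    curves[r, ] <- predict_length_core(kind, f$estimates[["L_inf"]],
                                       f$estimates[["k"]], f$estimates[["L0"]], ages)
  }
  if (failed > replicates / 2) {
    stop(sprintf("bootstrap failed: %d of %d replicate fits did not converge",
                 failed, replicates), call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(curves, 2, stats::quantile, probs = probs, na.rm = TRUE)
  structure(list(band = data.frame(age = ages, lower = qs[1, ], upper = qs[2, ]),
                 replicates = replicates, failed = failed,
                 level = level, seed = seed),
            class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("Bootstrap %g%% band: %d replicates (%d failed), ages %.3g-%.3g\n",
              100 * x$level, x$replicates, x$failed,
              min(x$band$age), max(x$band$age)))
  invisible(x)
}
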