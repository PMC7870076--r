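# Information-criterion machinery for the multi-model comparison:
# AIC / delta-AIC / AIC weights for the frequentist arm, and LOOIC via
# Pareto-smoothed importance sampling (PSIS) for the Bayesian arm. The PSIS
# smoothing follows the standard published algorithm: importance ratios
# 1 / p(y_i | theta_s), generalised-Pareto fit (Zhang & Stephens profile
# method) to the largest 20% of ratios, tail replaced by expected order
# statistics of the fitted distribution, per-observation shape diagnostic
# k-hat with a warning above 0.7.

#' Akaike information criterion for a least-squares growth fit
#'
#' `AIC = n * log(sigma2) + 2 * (n_params + 1)`, where `sigma2` is the
#' maximum-likelihood residual variance RSS/n and the `+ 1` counts the
#' variance as an estimated parameter.
#'
#' @param n Number of observations.
#' @param sigma2 Residual variance (RSS/n) of the fit, > 0.
#' @param n_params Number of estimated curve parameters (the variance is
#'   added internally).
#' @return The AIC value.
#' @examples
#' aic(n = 100, sigma2 = 4, n_params = 3)
#' @export
aic <- function(n, sigma2, n_params) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  n * log(sigma2) + 2 * (n_params + 1)
}

#' Information-criterion weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = value_i - min(value)`. Applies identically to AIC and LOOIC
#' values; an infinite criterion value receives weight 0.
#'
#' @param values Numeric vector of criterion values (at least one finite).
#' @return Numeric vector of weights summing to 1.
#' @examples
#' ic_weights(c(100, 102))
#' @export
ic_weights <- function(values) {
  if (!any(is.finite(values))) stop("need at least one finite criterion value", call. = FALSE)
  delta <- values - min(values[is.finite(values)])
  w <- exp(-delta / 2)
  w[!is.finite(values)] <- 0
  w / sum(w)
}

# Zhang & Stephens (2009) posterior-profile estimate of the generalised
# Pareto shape k and scale sigma for exceedances x > 0, with the weak
# shape regularisation commonly used for importance-ratio tails.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  N <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(N))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  bs <- 1 / x[N] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- N * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  sigma <- -k / b
  if (wip) k <- (N * k + 5) / (N + 10)  # shrink shape toward 0.5 (10 pseudo-draws)
  list(k = k, sigma = sigma)
}

# Generalised Pareto quantile function (location 0).
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one vector of log importance ratios. Returns the smoothed
# log weights (same ordering) and the tail-shape diagnostic k-hat.
psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(tail_frac * S)
  khat <- -Inf
  if (M >= 5L) {
    ord <- order(lw)
    tail_ids <- ord[seq.int(S - M + 1L, S)]
    cutoff <- exp(lw[ord[S - M]])
    exceed <- exp(lw[tail_ids]) - cutoff
    if (max(exceed) > sqrt(.Machine$double.eps)) {
      fit <- gpd_fit(exceed[exceed > 0])
      khat <- fit$k
      if (is.finite(fit$k) && is.finite(fit$sigma) && fit$sigma > 0) {
        # replace the tail by expected order statistics of the fitted GPD,
        # capped at the largest raw weight
        p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / M
        smoothed <- cutoff + qgpd(p, fit$k, fit$sigma)
        lw[tail_ids] <- pmin(log(smoothed), 0)
      }
    }
  }
  list(log_weights = lw - max(lw), khat = khat)
}

#' PSIS approximation to leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out cross-validation from a matrix of per-draw, per-observation
#' log-likelihoods, using Pareto-smoothed importance sampling, and reports
#' `LOOIC = -2 * elpd_loo` on the deviance scale used for model selection.
#'
#' @param log_lik Matrix of pointwise log-likelihoods (rows: posterior draws,
#'   at least 100; columns: observations), or a `growth_mcmc_fit`.
#' @param warn_k Pareto shape threshold above which an observation's
#'   importance weights are flagged as unreliable (default 0.7).
#' @return An object of class `psis_loo` with `elpd_loo`, `looic`, `se`
#'   (Monte-Carlo SE of both, on their respective scales), `pointwise`
#'   (per-observation elpd), and `pareto_k`.
#' @export
psis_loo <- function(log_lik, warn_k = 0.7) {
  if (inherits(log_lik, "growth_mcmc_fit")) log_lik <- log_lik_matrix(log_lik)
  if (!is.matrix(log_lik)) stop("`log_lik` must be a draws x observations matrix", call. = FALSE)
  if (any(!is.finite(log_lik))) stop("non-finite entries in log-likelihood matrix", call. = FALSE)
  S <- nrow(log_lik); n <- ncol(log_lik)
  if (S < 100L) stop("need at least 100 posterior draws for PSIS-LOO", call. = FALSE)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-log_lik[, i])
    lw <- sm$log_weights
    elpd_i[i] <- log_sum_exp(lw + log_lik[, i]) - log_sum_exp(lw)
    khat[i] <- sm$khat
  }
  if (any(khat > warn_k)) {
    warning(sprintf("%d of %d observations have Pareto k-hat > %.2f; PSIS-LOO may be unreliable for them",
                    sum(khat > warn_k), n, warn_k), call. = FALSE)
  }
  elpd <- sum(elpd_i)
  se_elpd <- sqrt(n * stats::var(elpd_i))
  structure(list(elpd_loo = elpd, looic = -2 * elpd,
                 se = se_elpd, looic_se = 2 * se_elpd,
                 pointwise = elpd_i, pareto_k = khat, n = n, n_draws = S),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.2f (SE %.2f), LOOIC = %.2f (SE %.2f), n = %d, draws = %d\n",
              x$elpd_loo, x$se, x$looic, x$looic_se, x$n, x$n_draws))
  cat(sprintf("Pareto k-hat: max = %.3f, %d observation(s) > 0.7\n",
              max(x$pareto_k), sum(x$pareto_k > 0.7)))
  invisible(x)
}

#' Rank candidate growth models
#'
#' Builds the model-selection table for a set of fits to the same dataset:
#' LOOIC / delta / LOOICw for Bayesian fits (via [psis_loo()]) or
#' AIC / delta / AICw for least-squares fits. Rows are sorted best first;
#' ties keep the input order.
#'
#' @param fits List of two or more `growth_mcmc_fit` or two or more
#'   `growth_nls_fit` objects fitted to the same data.
#' @return A data frame of class `growth_model_comparison` with columns
#'   `model`, `criterion`, `value`, `delta`, `weight`, `pareto_k_max`
#'   (NA for AIC rows).
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop("`fits` must be a list of at least two fitted models", call. = FALSE)
  }
  is_mcmc <- vapply(fits, inherits, logical(1), what = "growth_mcmc_fit")
  is_nls <- vapply(fits, inherits, logical(1), what = "growth_nls_fit")
  if (!(all(is_mcmc) || all(is_nls))) {
    stop("all fits must be of the same arm (all MCMC or all NLS)", call. = FALSE)
  }
  ns <- vapply(fits, function(f) if (inherits(f, "growth_mcmc_fit")) nrow(f$data) else f$n,
               numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("fits were made on datasets of differing size; compare fits of one dataset only",
         call. = FALSE)
  }
  models <- vapply(fits, function(f) f$kind, character(1))
  if (all(is_mcmc)) {
    loos <- lapply(fits, psis_loo)
    value <- vapply(loos, function(l) l$looic, numeric(1))
    kmax <- vapply(loos, function(l) max(l$pareto_k), numeric(1))
    criterion <- "LOOIC"
  } else {
    value <- vapply(fits, function(f) {
      if (!f$converged) return(Inf)
      aic(f$n, f$sigma2, f$n_free_params)
    }, numeric(1))
    kmax <- rep(NA_real_, length(fits))
    criterion <- "AIC"
  }
  delta <- value - min(value[is.finite(value)])
  weight <- ic_weights(value)
  tab <- data.frame(model = models, criterion = criterion, value = value,
                    delta = delta, weight = weight, pareto_k_max = kmax,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$value), , drop = FALSE]  # stable: ties keep input order
  rownames(tab) <- NULL
  class(tab) <- c("growth_model_comparison", "data.frame")
  tab
}

#' Write a model-comparison table to CSV
#'
#' @param comparison A [compare_models()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  stopifnot(inherits(comparison, "growth_model_comparison"))
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
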