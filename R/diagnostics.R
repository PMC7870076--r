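# Convergence diagnostics for the MCMC arm: split-chain Gelman-Rubin
# statistic, effective sample size and the autocorrelation check that
# motivates thinning.

# Accept a growth_mcmc_fit, a coda::mcmc.list, or a plain list of per-chain
# numeric matrices with identical column names.
chain_matrices <- function(x) {
  if (inherits(x, "growth_mcmc_fit")) return(x$draws)
  if (inherits(x, "mcmc.list")) return(lapply(x, as.matrix))
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) return(x)
  if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) {
    return(lapply(x, function(v) matrix(v, ncol = 1, dimnames = list(NULL, "par"))))
  }
  stop("expected a growth_mcmc_fit, mcmc.list, or list of per-chain matrices",
       call. = FALSE)
}

split_rhat_one <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n2 <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[seq_len(n2)], ch[seq.int(length(ch) - n2 + 1, length(ch))]))
  }
  n2 <- length(halves[[1]])
  mu <- vapply(halves, mean, numeric(1))
  s2 <- vapply(halves, stats::var, numeric(1))
  W <- mean(s2)
  B <- n2 * stats::var(mu)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting every chain in
#' half, so that a trending single chain is detected as disagreement between
#' its own halves. Values near 1 indicate convergence; the fitting path warns
#' above 1.01.
#'
#' @param x A `growth_mcmc_fit`, a `coda::mcmc.list`, or a list of per-chain
#'   draw matrices (>= 2 chains, >= 4 retained draws per chain).
#' @return Named numeric vector of split-Rhat values, one per parameter.
#' @export
gelman_rubin <- function(x) {
  chains <- chain_matrices(x)
  if (length(chains) < 2L) {
    stop("Gelman-Rubin diagnostic requires at least 2 chains", call. = FALSE)
  }
  if (any(vapply(chains, nrow, integer(1)) < 4L)) {
    stop("need at least 4 retained draws per chain", call. = FALSE)
  }
  pars <- colnames(chains[[1]])
  out <- vapply(pars, function(p) {
    split_rhat_one(lapply(chains, function(m) m[, p]))
  }, numeric(1))
  names(out) <- pars
  out
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws per parameter,
#' pooled across chains (computed with `coda::effectiveSize`).
#'
#' @inheritParams gelman_rubin
#' @return Named numeric vector of effective sample sizes.
#' @export
effective_size <- function(x) {
  chains <- chain_matrices(x)
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  out <- coda::effectiveSize(ml)
  names(out) <- colnames(chains[[1]])
  out
}

#' Autocorrelation check of retained draws
#'
#' Sample autocorrelation function per parameter (averaged across chains),
#' with a flag raised when the lag-1 autocorrelation of any parameter exceeds
#' `threshold`; a raised flag is the cue to thin ([thin_draws()]) and extend
#' the chains.
#'
#' @inheritParams gelman_rubin
#' @param max_lag Largest lag to report (default 20).
#' @param threshold Lag-1 flag threshold (default 0.3).
#' @return List with `acf` (matrix, lags 1..max_lag by parameter), `lag1`
#'   (named vector), `flag` (logical) and `threshold`.
#' @export
autocorrelation_check <- function(x, max_lag = 20, threshold = 0.3) {
  chains <- chain_matrices(x)
  if (any(vapply(chains, nrow, integer(1)) < max_lag + 1L)) {
    stop(sprintf("need at least max_lag + 1 = %d retained draws per chain", max_lag + 1L),
         call. = FALSE)
  }
  pars <- colnames(chains[[1]])
  acfs <- vapply(pars, function(p) {
    per_chain <- vapply(chains, function(m) {
      stats::acf(m[, p], lag.max = max_lag, plot = FALSE,
                 demean = TRUE)$acf[-1, 1, 1]
    }, numeric(max_lag))
    rowMeans(per_chain)
  }, numeric(max_lag))
  rownames(acfs) <- paste0("lag", seq_len(max_lag))
  lag1 <- acfs[1, ]
  list(acf = acfs, lag1 = lag1,
       flag = any(lag1 > threshold, na.rm = TRUE), threshold = threshold)
}
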