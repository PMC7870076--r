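# Shared length-at-age curves and the normal-residual likelihood used by both
# the Bayesian and frequentist fitting arms. All three candidate models share
# the biologically interpretable parameters L0 (length-at-birth) and L_inf
# (asymptotic length), so the same priors and the same parameter vector apply
# across candidates.

#' Candidate growth model names
#'
#' The three length-at-age models commonly fitted in a multi-model framework:
#' von Bertalanffy (`"vbgm"`), Gompertz (`"gompertz"`) and logistic
#' (`"logistic"`). All three are parameterised through length-at-birth `L0`
#' and asymptotic length `L_inf` (never `t0`), so parameters other than the
#' growth completion rate `k` are directly comparable between candidates.
#'
#' @return Character vector of the three model names.
#' @export
growth_model_kinds <- function() c("vbgm", "gompertz", "logistic")

#' Normalise a growth model name
#'
#' Case-insensitive matching of a model name against [growth_model_kinds()].
#'
#' @param kind Character scalar, e.g. `"VBGM"` or `"logistic"`.
#' @return The matched lower-case model name.
#' @export
match_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || is.na(kind)) {
    stop("`kind` must be a single character string", call. = FALSE)
  }
  k <- tolower(trimws(kind))
  if (!k %in% growth_model_kinds()) {
    stop(sprintf("unknown growth model '%s'; expected one of %s",
                 kind, paste(growth_model_kinds(), collapse = ", ")),
         call. = FALSE)
  }
  k
}

# Minimum L0 (cm) at which the Gompertz and logistic curves are evaluated.
# Both involve log(L_inf/L0) or a ratio in L0, so a hard zero is undefined;
# fitting paths clamp proposals to this floor rather than erroring because a
# continuous prior puts zero mass on the point L0 = 0.
L0_FLOOR <- 1e-6

#' Growth parameter vector
#'
#' Bundles the four parameters shared by every candidate model: asymptotic
#' length `L_inf` (cm), growth completion rate `k` (per year), length-at-birth
#' `L0` (cm) and the residual standard deviation `sigma` (cm).
#'
#' @param L_inf Asymptotic length in cm, > 0.
#' @param k Growth completion parameter in 1/yr, > 0. Not comparable between
#'   model kinds.
#' @param L0 Length-at-birth in cm, >= 0 and < `L_inf`.
#' @param sigma Residual standard deviation in cm, > 0.
#' @return An object of class `growth_params` (a named list).
#' @examples
#' growth_params(L_inf = 250, k = 0.2, L0 = 0, sigma = 10)
#' @export
growth_params <- function(L_inf, k, L0 = 0, sigma = 1) {
  p <- list(L_inf = as.numeric(L_inf), k = as.numeric(k),
            L0 = as.numeric(L0), sigma = as.numeric(sigma))
  if (any(!vapply(p, is.finite, logical(1)))) {
    stop("all growth parameters must be finite", call. = FALSE)
  }
  if (p$L_inf <= 0) stop("L_inf must be > 0", call. = FALSE)
  if (p$k <= 0) stop("k must be > 0", call. = FALSE)
  if (p$L0 < 0) stop("L0 must be >= 0", call. = FALSE)
  if (p$L0 >= p$L_inf) stop("L0 must be smaller than L_inf", call. = FALSE)
  if (p$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(p, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: L_inf = %.4g cm, k = %.4g /yr, L0 = %.4g cm, sigma = %.4g cm\n",
              x$L_inf, x$k, x$L0, x$sigma))
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    return(growth_params(x[["L_inf"]], x[["k"]], x[["L0"]],
                         if ("sigma" %in% names(x)) x[["sigma"]] else 1))
  }
  if (is.list(x)) {
    return(growth_params(x$L_inf, x$k, x$L0, if (is.null(x$sigma)) 1 else x$sigma))
  }
  stop("cannot interpret `params` as growth parameters", call. = FALSE)
}

# Curve evaluation without user-facing validation; L0 is clamped to the
# evaluation floor for the two kinds whose equations are singular at L0 = 0.
# This is the path used by the samplers and optimisers.
predict_length_core <- function(kind, L_inf, k, L0, age) {
  switch(kind,
    vbgm = L_inf - (L_inf - L0) * exp(-k * age),
    gompertz = {
      L0c <- max(L0, L0_FLOOR)
      L0c * exp(log(L_inf / L0c) * (1 - exp(-k * age)))
    },
    logistic = {
      L0c <- max(L0, L0_FLOOR)
      (L_inf * L0c * exp(k * age)) / (L_inf + L0c * (exp(k * age) - 1))
    },
    stop("unknown kind"))
}

#' Predicted length-at-age
#'
#' Evaluates the selected growth curve at one or more ages. All three
#' equations equal `L0` exactly at age 0 and approach `L_inf` monotonically
#' with age:
#' \describe{
#'   \item{vbgm}{`La = L_inf - (L_inf - L0) * exp(-k * a)`}
#'   \item{gompertz}{`La = L0 * exp(log(L_inf / L0) * (1 - exp(-k * a)))`}
#'   \item{logistic}{`La = (L_inf * L0 * exp(k * a)) / (L_inf + L0 * (exp(k * a) - 1))`}
#' }
#'
#' @param kind Growth model name, see [growth_model_kinds()].
#' @param params A [growth_params()] object (or coercible named list/vector).
#' @param age Numeric vector of ages in years, >= 0. Ages are continuous;
#'   integer ages are a convention of the sampling simulator only.
#' @return Numeric vector of predicted lengths (cm), same length as `age`.
#' @examples
#' predict_length("vbgm", growth_params(250, 0.2, 0, 10), age = 5)
#' @export
predict_length <- function(kind, params, age) {
  kind <- match_kind(kind)
  p <- as_growth_params(params)
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be finite and >= 0", call. = FALSE)
  }
  if (kind != "vbgm" && p$L0 < L0_FLOOR) {
    stop(sprintf("the %s curve requires L0 >= %g cm (log/ratio of L0 appears in its equation)",
                 kind, L0_FLOOR), call. = FALSE)
  }
  predict_length_core(kind, p$L_inf, p$k, p$L0, age)
}

#' Log-likelihood of a length-at-age dataset
#'
#' Sum over observations of the normal log-density of observed length with
#' mean [predict_length()] at the observed age and standard deviation
#' `params$sigma` (the homoscedastic normal residual structure used by both
#' fitting arms).
#'
#' @inheritParams predict_length
#' @param data A [growth_data()] data frame with columns `age` and `length`.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(kind, params, data) {
  kind <- match_kind(kind)
  p <- as_growth_params(params)
  data <- as_growth_data(data)
  mu <- predict_length(kind, p, data$age)
  sum(stats::dnorm(data$length, mean = mu, sd = p$sigma, log = TRUE))
}

# Per-observation log-density rows for a matrix of posterior draws
# (rows: draws with columns L_inf, k, L0, sigma). Uses the clamped evaluation
# path, matching what the sampler saw. Returns draws x n matrix.
pointwise_log_lik <- function(kind, draws, data) {
  n <- nrow(data)
  S <- nrow(draws)
  L_inf <- draws[, "L_inf"]; k <- draws[, "k"]
  L0 <- pmax(draws[, "L0"], if (kind == "vbgm") 0 else L0_FLOOR)
  sigma <- draws[, "sigma"]
  out <- matrix(NA_real_, S, n)
  for (i in seq_len(n)) {
    a <- data$age[i]
    mu <- switch(kind,
      vbgm = L_inf - (L_inf - L0) * exp(-k * a),
      gompertz = L0 * exp(log(L_inf / L0) * (1 - exp(-k * a))),
      logistic = (L_inf * L0 * exp(k * a)) / (L_inf + L0 * (exp(k * a) - 1)))
    out[, i] <- stats::dnorm(data$length[i], mu, sigma, log = TRUE)
  }
  out
}
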