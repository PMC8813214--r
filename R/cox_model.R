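#' Fit a Cox proportional hazards model
#'
#' Survival stage of the PLS-Cox benchmark: Cox partial-likelihood fitting
#' with Efron tie handling, via \code{survival::coxph}, plus a Breslow-type
#' baseline cumulative hazard and partial-likelihood information criteria.
#'
#' AIC/BIC are computed from the partial likelihood; comparing these with
#' full-likelihood criteria from parametric fits mixes likelihood types and
#' is reported as such, not endorsed (see the package vignette).
#'
#' @param data A \code{\link{survival_data}} with at least one event and
#'   fewer predictors than subjects.
#' @return An object of class \code{cox_fit}: \code{beta},
#'   \code{partial_log_likelihood}, \code{n_parameters}, \code{aic},
#'   \code{bic}, \code{baseline_cumulative_hazard} (step function of time),
#'   \code{converged}, \code{n}, \code{n_events}, and the underlying
#'   \code{coxph} object as \code{engine}.
#' @export
fit_cox <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  n <- length(data$time)
  p <- ncol(data$covariates)
  if (sum(data$status) == 0) stop("no events; Cox model undefined")
  if (p == 0) stop("Cox model requires at least one predictor")
  if (p >= n)
    stop("refusing an unregularized Cox fit with p = ", p, " >= n = ", n,
         "; reduce dimension first (e.g. PLS components)")
  y <- survival::Surv(data$time, data$status)
  X <- data$covariates
  cf <- survival::coxph(y ~ X, ties = "efron")
  beta <- stats::setNames(unname(stats::coef(cf)), colnames(X))
  converged <- !any(is.na(beta)) && all(is.finite(beta)) &&
    all(sqrt(diag(cf$var)) < 1e3)  # flags monotone-likelihood divergence
  pll <- cf$loglik[length(cf$loglik)]
  bh <- survival::basehaz(cf, centered = FALSE)
  base_fun <- stats::stepfun(bh$time, c(0, bh$hazard))
  structure(list(
    beta = beta, partial_log_likelihood = pll, n_parameters = p,
    aic = -2 * pll + 2 * p, bic = -2 * pll + log(n) * p,
    baseline_cumulative_hazard = base_fun,
    converged = converged, n = n, n_events = sum(data$status),
    engine = cf),
    class = "cox_fit")
}

#' Partial-likelihood information criteria for a Cox fit
#' @param fit A \code{cox_fit}.
#' @param n Number of subjects (defaults to the fitting sample size).
#' @return Named vector \code{c(aic, bic)}.
#' @export
cox_information_criteria <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "cox_fit"))
  information_criteria(fit, n)
}

#' Efron partial log-likelihood of fixed coefficients on (new) data
#'
#' Evaluates the Cox partial likelihood at the fit's coefficients on an
#' arbitrary dataset; used for out-of-sample scoring.
#'
#' @param fit A \code{cox_fit}.
#' @param data A \code{survival_data} with matching predictor columns.
#' @return Scalar partial log-likelihood.
#' @export
cox_log_likelihood <- function(fit, data) {
  stopifnot(inherits(fit, "cox_fit"), inherits(data, "survival_data"))
  if (ncol(data$covariates) != length(fit$beta))
    stop("predictor count mismatch")
  y <- survival::Surv(data$time, data$status)
  X <- data$covariates
  f0 <- survival::coxph(y ~ X, ties = "efron", init = unname(fit$beta),
                        control = survival::coxph.control(iter.max = 0))
  f0$loglik[length(f0$loglik)]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties)\n")
  cat("  n =", x$n, " events =", x$n_events, "\n")
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  cat("  partial logLik =", format(x$partial_log_likelihood, digits = 7),
      " AIC =", format(x$aic, digits = 7),
      " BIC =", format(x$bic, digits = 7), "\n")
  if (!x$converged) cat("  WARNING: possible monotone-likelihood divergence\n")
  invisible(x)
}
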