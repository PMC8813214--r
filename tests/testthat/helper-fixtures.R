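# Shared fixtures: everything generated in code, no stored data.

# small uncorrelated survival dataset with a handful of covariates
make_small_data <- function(n = 200, p = 3, beta = NULL, seed = 1) {
  if (is.null(beta)) beta <- numeric(p)
  spec <- simulation_spec(n = n, p = p, corr_max = 0, true_beta = beta,
                          seed = seed)
  simulate_dataset(spec)
}

# covariate-free Weibull data under the null configuration
make_null_weibull <- function(n = 1000, seed = 1, lambda = 0.1, gamma = 1.5,
                              horizon = 5) {
  spec <- simulation_spec(n = n, p = 1, corr_max = 0,
                          weibull_scale = lambda, weibull_shape = gamma,
                          censor_horizon = horizon, true_beta = 0,
                          seed = seed)
  d <- simulate_dataset(spec)
  survival_data(d$time, d$status)
}

# censored Weibull log-likelihood in the direct (lambda, gamma)
# parameterization -- textbook oracle, independent of the spline code path
weibull_censored_loglik <- function(par, time, status) {
  lambda <- exp(par[1]); gamma <- exp(par[2])
  h <- log(lambda) + log(gamma) + (gamma - 1) * log(time)
  H <- lambda * time^gamma
  sum(status * h - H)
}

# censored log-logistic log-likelihood: S(t) = 1 / (1 + lambda * t^gamma)
loglogistic_censored_loglik <- function(par, time, status) {
  lambda <- exp(par[1]); gamma <- exp(par[2])
  ltg <- log(lambda) + gamma * log(time)
  logS <- -log1p(exp(ltg))
  logf <- log(lambda) + log(gamma) + (gamma - 1) * log(time) + 2 * logS
  sum(status * logf + (1 - status) * logS)
}

# censored lognormal log-likelihood
lognormal_censored_loglik <- function(par, time, status) {
  mu <- par[1]; sigma <- exp(par[2])
  z <- (log(time) - mu) / sigma
  logf <- dnorm(z, log = TRUE) - log(sigma) - log(time)
  logS <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  sum(status * logf + (1 - status) * logS)
}

maximize2 <- function(fn, start = c(0, 0), ...) {
  opt <- optim(start, fn, ..., method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  opt
}
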