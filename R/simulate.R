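#' Specify a collinear-covariate Weibull survival simulation
#'
#' Defaults mirror the simulation design the package's model comparison is
#' built around: n = 100 subjects, p = 200 covariates with pairwise
#' correlations spanning 0 to 0.9, Weibull event times with scale 0.1 and
#' shape 1.5 under proportional hazards, and administrative censoring at 5
#' time units.
#'
#' The default true effect vector is sparse: the first
#' \code{min(10, p)} covariates at 0.2, the rest 0. Set
#' \code{true_beta = rep(0, p)} for a null (exactly Weibull-marginal)
#' configuration.
#'
#' @param n Number of subjects.
#' @param p Number of covariates.
#' @param corr_max Maximum pairwise correlation, in [0, 1).
#' @param weibull_scale Weibull scale parameter \eqn{\lambda > 0}.
#' @param weibull_shape Weibull shape parameter \eqn{\gamma > 0}.
#' @param censor_horizon Administrative censoring time.
#' @param true_beta Length-p vector of log hazard ratios.
#' @param seed Integer seed; every generated dataset is a deterministic
#'   function of the spec including this seed.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n = 100L, p = 200L, corr_max = 0.9,
                            weibull_scale = 0.1, weibull_shape = 1.5,
                            censor_horizon = 5, true_beta = NULL,
                            seed = 1L) {
  n <- as.integer(n); p <- as.integer(p)
  stopifnot(n >= 2, p >= 1, corr_max >= 0, corr_max < 1,
            weibull_scale > 0, weibull_shape > 0, censor_horizon > 0)
  if (is.null(true_beta)) {
    true_beta <- numeric(p)
    true_beta[seq_len(min(10L, p))] <- 0.2
  }
  stopifnot(length(true_beta) == p)
  structure(list(n = n, p = p, corr_max = corr_max,
                 weibull_scale = weibull_scale, weibull_shape = weibull_shape,
                 censor_horizon = censor_horizon, true_beta = true_beta,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate correlated Gaussian covariates
#'
#' Covariates are multivariate normal with unit variance and a
#' block-structured correlation target: the p columns are split into up to
#' 10 contiguous blocks, block b carrying first-order autoregressive
#' within-block correlation at level \eqn{\rho_b}, the \eqn{\rho_b} equally
#' spaced over [0, \code{corr_max}]. Cross-block correlation is 0, so
#' realized pairwise correlations span approximately 0 to \code{corr_max}.
#' The AR(1) construction guarantees a positive-definite target for any
#' \code{corr_max} < 1. Deterministic given \code{spec$seed}.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return Numeric \code{n x p} matrix with columns \code{x1..xp}.
#' @export
simulate_covariates <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p
  n_blocks <- min(10L, p)
  block_id <- sort(rep_len(seq_len(n_blocks), p))
  rho <- if (n_blocks == 1) spec$corr_max
         else seq(0, spec$corr_max, length.out = n_blocks)
  X <- matrix(0, n, p)
  for (b in seq_len(n_blocks)) {
    cols <- which(block_id == b)
    Z <- matrix(stats::rnorm(n * length(cols)), n, length(cols))
    Xb <- Z
    if (length(cols) > 1 && rho[b] > 0) {
      for (j in 2:length(cols))
        Xb[, j] <- rho[b] * Xb[, j - 1] + sqrt(1 - rho[b]^2) * Z[, j]
    }
    X[, cols] <- Xb
  }
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Simulate Weibull event times with administrative censoring
#'
#' Latent event times follow a proportional-hazards Weibull model,
#' \eqn{H(t|x) = \lambda t^\gamma e^{x'\beta}}, drawn by inverse transform:
#' \eqn{T = (-\ln U / (\lambda e^{x'\beta}))^{1/\gamma}} with U uniform.
#' Subjects with \eqn{T \ge} \code{censor_horizon} are censored at the
#' horizon. Deterministic given \code{spec$seed} (a stream offset keeps the
#' time draws independent of the covariate draws).
#'
#' @param X Covariate matrix with \code{spec$n} rows.
#' @param spec A \code{\link{simulation_spec}}.
#' @return A \code{\link{survival_data}} object.
#' @export
simulate_times <- function(X, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  X <- as.matrix(X)
  if (nrow(X) != spec$n) stop("X must have spec$n rows")
  set.seed((spec$seed + 9871L) %% .Machine$integer.max)
  lp <- if (ncol(X)) drop(X %*% spec$true_beta) else numeric(spec$n)
  u <- stats::runif(spec$n)
  latent <- .weibull_ph_inverse(u, lp, spec$weibull_scale, spec$weibull_shape)
  status <- as.integer(latent < spec$censor_horizon)
  time <- pmin(latent, spec$censor_horizon)
  survival_data(time, status, X)
}

# inverse transform under the PH-Weibull model: solve S(t|x) = u for t,
# with S(t|x) = exp(-lambda * t^gamma * exp(lp))
.weibull_ph_inverse <- function(u, lp, lambda, gamma) {
  if (lambda <= 0 || gamma <= 0) stop("Weibull parameters must be positive")
  (-log(u) / (lambda * exp(lp)))^(1 / gamma)
}

#' Simulate a complete survival dataset
#'
#' Convenience wrapper: \code{\link{simulate_covariates}} followed by
#' \code{\link{simulate_times}}.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A \code{\link{survival_data}} object.
#' @export
simulate_dataset <- function(spec) {
  simulate_times(simulate_covariates(spec), spec)
}

#' Split a dataset into training and test parts
#'
#' Uniform random partition without replacement; the training part gets
#' \code{ceiling(n * train_fraction)} subjects. Deterministic given
#' \code{seed}.
#'
#' @param data A \code{\link{survival_data}}.
#' @param train_fraction Fraction of subjects assigned to training,
#'   in (0, 1); default 0.7.
#' @param seed Integer seed for the partition.
#' @return List with elements \code{train} and \code{test}, both
#'   \code{survival_data}; no subject appears in both.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(data, "survival_data"),
            train_fraction > 0, train_fraction < 1)
  n <- length(data$time)
  set.seed(as.integer(seed))
  idx <- sample.int(n, size = ceiling(n * train_fraction))
  train <- subset_rows(data, idx)
  if (sum(train$status) < 2)
    stop("training partition has fewer than 2 events; use another seed")
  list(train = train, test = subset_rows(data, -idx))
}
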