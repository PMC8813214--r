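test_that("information criteria follow the AIC/BIC definitions", {
  fake <- structure(list(log_likelihood = -100, n_parameters = 3, n = 100),
                    class = "rp_fit")
  ic <- information_criteria(fake)
  expect_equal(unname(ic["aic"]), 206)
  expect_equal(unname(ic["bic"]), 200 + 3 * log(100))
})

test_that("no-knot fits agree with independent direct-parameterization MLEs", {
  oracles <- list(hazard = weibull_censored_loglik,
                  odds = loglogistic_censored_loglik,
                  normal = lognormal_censored_loglik)
  starts <- list(hazard = c(log(0.1), log(1.5)),
                 odds = c(log(0.1), log(1.5)),
                 normal = c(0.5, 0))
  d <- make_null_weibull(n = 500, seed = 33)
  for (sc in names(oracles)) {
    fit <- fit_rp(d, scale = sc, n_internal_knots = 0)
    expect_true(fit$converged)
    oracle <- maximize2(function(p) oracles[[sc]](p, d$time, d$status),
                        start = starts[[sc]])
    expect_equal(fit$log_likelihood, oracle$value, tolerance = 1e-6)
  }
})

test_that("no-knot fits reproduce survreg's censored parametric likelihoods", {
  d <- make_null_weibull(n = 600, seed = 8)
  df <- data.frame(time = d$time, status = d$status)
  dists <- c(hazard = "weibull", odds = "loglogistic", normal = "lognormal")
  for (sc in names(dists)) {
    fit <- fit_rp(d, scale = sc, n_internal_knots = 0)
    sr <- survival::survreg(survival::Surv(time, status) ~ 1, data = df,
                            dist = dists[[sc]])
    expect_equal(fit$log_likelihood, sr$loglik[1], tolerance = 1e-6)
  }
})

test_that("one-internal-knot hazard fit matches flexsurvspline", {
  skip_if_not_installed("flexsurv")
  spec <- simulation_spec(n = 400, p = 1, true_beta = 0.3, seed = 17)
  d <- simulate_dataset(spec)
  fit <- fit_rp(d, scale = "hazard", n_internal_knots = 1)
  fs <- flexsurv::flexsurvspline(
    survival::Surv(time, status) ~ x1,
    data = data.frame(time = d$time, status = d$status,
                      x1 = d$covariates[, 1]),
    k = 1, scale = "hazard")
  expect_equal(fit$log_likelihood, fs$loglik, tolerance = 1e-4)
  expect_equal(unname(fit$beta["x1"]), unname(coef(fs)["x1"]),
               tolerance = 1e-3)
})

test_that("adding an internal knot never lowers the maximized likelihood", {
  for (seed in 1:3) {
    d <- make_null_weibull(n = 300, seed = seed)
    for (sc in c("hazard", "odds", "normal")) {
      f0 <- fit_rp(d, sc, 0)
      f1 <- fit_rp(d, sc, 1)
      expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-6)
    }
  }
})

test_that("cumulative hazard prediction has the Weibull closed form", {
  b <- spline_basis(place_knots(log(c(0.2, 5)), 0))
  fit <- structure(list(scale = "hazard", basis = b,
                        eta_coefficients = c(log(0.1), 1.5),
                        beta = numeric(0)),
                   class = "rp_fit")
  expect_equal(predict_cumulative_hazard(fit, 1), 0.1)
  expect_equal(predict_cumulative_hazard(fit, 4), 0.1 * 4^1.5)
  expect_equal(predict_survival(fit, 1), exp(-0.1))
})

test_that("cumulative hazard equals -log survival on every scale", {
  spec <- simulation_spec(n = 300, p = 2, true_beta = c(0.4, 0), seed = 5)
  d <- simulate_dataset(spec)
  times <- c(0.05, 0.5, 1, 3, 4.9, 8)  # includes extrapolation beyond data
  for (sc in c("hazard", "odds", "normal")) {
    fit <- fit_rp(d, sc, 1)
    H <- predict_cumulative_hazard(fit, times, c(0.5, -0.2))
    S <- predict_survival(fit, times, c(0.5, -0.2))
    expect_equal(H, -log(S), tolerance = 1e-10)
    expect_true(all(H >= 0))
    expect_true(all(diff(H) > 0))
  }
})

test_that("regression effect sign is recovered under a binary covariate", {
  hits <- 0
  for (seed in 1:10) {
    spec <- simulation_spec(n = 500, p = 1, true_beta = 0.5, seed = seed)
    set.seed(seed + 500)
    X <- matrix(rbinom(500, 1, 0.5), ncol = 1,
                dimnames = list(NULL, "x1"))
    d <- simulate_times(X, spec)
    fit <- fit_rp(d, "hazard", 0)
    if (fit$beta["x1"] > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate inputs are refused with informative errors", {
  d <- make_small_data(n = 50, p = 2)
  all_cens <- survival_data(d$time, rep(0, 50), d$covariates)
  expect_error(fit_rp(all_cens, "hazard", 0), "censored")
  wide <- survival_data(d$time, d$status,
                        matrix(rnorm(50 * 60), 50, 60))
  expect_error(fit_rp(wide, "hazard", 0), "refusing")
})

test_that("out-of-sample log-likelihood matches the training objective", {
  d <- make_small_data(n = 250, p = 2, beta = c(0.3, 0), seed = 9)
  fit <- fit_rp(d, "odds", 1)
  expect_equal(rp_log_likelihood(fit, d), fit$log_likelihood,
               tolerance = 1e-8)
})

test_that("delta-method variances are available and positive", {
  d <- make_small_data(n = 300, p = 1, beta = 0.4, seed = 2)
  fit <- fit_rp(d, "hazard", 0)
  expect_false(is.null(fit$vcov))
  expect_true(all(diag(fit$vcov) > 0))
})
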