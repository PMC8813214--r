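test_that("one-covariate PLS: the score is the standardized covariate", {
  set.seed(1)
  x <- matrix(rnorm(40), ncol = 1)
  y <- rnorm(40)
  dec <- extract_components(x, y, 1)
  xs <- as.numeric(scale(x))
  agree <- max(abs(dec$scores[, 1] - xs))
  flipped <- max(abs(dec$scores[, 1] + xs))
  expect_lt(min(agree, flipped), 1e-10)
})

test_that("full-component PLS on a full-rank design recovers OLS", {
  set.seed(2)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  dec <- extract_components(X, y, p)
  b_pls <- drop(dec$projection %*% dec$y_loadings)
  Xs <- scale(X); ys <- as.numeric(scale(y))
  b_ols <- unname(coef(lm(ys ~ Xs))[-1])
  expect_equal(unname(b_pls), b_ols, tolerance = 1e-8)
})

test_that("weights and scores match the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 10), 50, 10)
    y <- rnorm(50)
    C <- 3
    dec <- extract_components(X, y, C)
    ref <- mixOmics::pls(X, y, ncomp = C, mode = "regression", scale = TRUE)
    for (c in seq_len(C)) {
      sgn <- sign(sum(dec$weights[, c] * ref$loadings$X[, c]))
      expect_equal(unname(dec$weights[, c]),
                   unname(sgn * ref$loadings$X[, c]), tolerance = 1e-6)
      expect_equal(unname(dec$scores[, c]),
                   unname(sgn * ref$variates$X[, c]), tolerance = 1e-6)
    }
  }
})

test_that("scores are mutually orthogonal and projection round-trips", {
  set.seed(3)
  spec <- simulation_spec(n = 100, p = 40, corr_max = 0.9, seed = 3)
  d <- simulate_dataset(spec)
  dec <- extract_components(d$covariates, log(d$time), 4)
  G <- crossprod(dec$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_equal(project(dec, d$covariates), dec$scores, tolerance = 1e-8)
  # projecting the training mean row gives the zero score vector
  expect_equal(drop(project(dec, matrix(dec$center, nrow = 1))),
               setNames(rep(0, 4), colnames(dec$scores)), tolerance = 1e-10)
  # held-out projection is linear in the stored weights: fixed-weight check
  new <- matrix(rnorm(5 * 40), 5, 40)
  Xs <- sweep(sweep(new, 2, dec$center), 2, dec$scale_factors, "/")
  expect_equal(project(dec, new), Xs %*% dec$projection)
})

test_that("invalid extractions are refused with informative errors", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3)
  colnames(X) <- c("a", "b", "c")
  X[, 2] <- 1
  expect_error(extract_components(X, rnorm(30), 2), "b")
  X2 <- matrix(rnorm(20 * 3), 20, 3)
  X2 <- cbind(X2, X2[, 1])  # rank 3, 4 columns
  expect_error(extract_components(X2, rnorm(20), 4), "rank")
  expect_error(extract_components(X2, rnorm(20), 0), "C")
})

test_that("back-projection is consistent: scores x beta = Xs x b", {
  spec <- simulation_spec(n = 120, p = 30, corr_max = 0.8, seed = 6)
  d <- simulate_dataset(spec)
  cf <- fit_pls_spline(d, C = 3, scale = "hazard", n_internal_knots = 0)
  dec <- cf$decomposition
  Xs <- sweep(sweep(d$covariates, 2, dec$center), 2, dec$scale_factors, "/")
  lhs <- drop(dec$scores %*% cf$survival_stage$beta)
  rhs <- drop(Xs %*% cf$covariate_coefficients)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("composite fit equals a direct RP fit when C spans the design", {
  set.seed(7)
  spec <- simulation_spec(n = 150, p = 4, corr_max = 0,
                          true_beta = c(0.3, -0.2, 0, 0), seed = 7)
  d <- simulate_dataset(spec)
  cf <- fit_pls_spline(d, C = 4, scale = "hazard", n_internal_knots = 0)
  direct <- fit_rp(survival_data(d$time, d$status, scale(d$covariates)),
                   "hazard", 0)
  expect_equal(cf$survival_stage$log_likelihood, direct$log_likelihood,
               tolerance = 1e-4)
})

test_that("permuting covariate columns permutes coefficients identically", {
  spec <- simulation_spec(n = 90, p = 12, corr_max = 0.5, seed = 8)
  d <- simulate_dataset(spec)
  cf1 <- fit_pls_spline(d, C = 2, scale = "odds", n_internal_knots = 0)
  perm <- c(5:12, 1:4)
  d2 <- survival_data(d$time, d$status, d$covariates[, perm])
  cf2 <- fit_pls_spline(d2, C = 2, scale = "odds", n_internal_knots = 0)
  expect_equal(cf1$survival_stage$log_likelihood,
               cf2$survival_stage$log_likelihood, tolerance = 1e-6)
  expect_equal(unname(cf2$covariate_coefficients),
               unname(cf1$covariate_coefficients[perm]), tolerance = 1e-6)
})

test_that("spline and Cox composites share one decomposition", {
  spec <- simulation_spec(n = 100, p = 25, corr_max = 0.7, seed = 9)
  d <- simulate_dataset(spec)
  a <- fit_pls_spline(d, C = 2, scale = "hazard", n_internal_knots = 0)
  b <- fit_pls_cox(d, C = 2)
  expect_equal(a$decomposition$weights, b$decomposition$weights)
  expect_equal(a$decomposition$scores, b$decomposition$scores)
})

test_that("PLS-Cox on one covariate reduces to Cox on the standardized covariate", {
  set.seed(10)
  spec <- simulation_spec(n = 120, p = 1, true_beta = 0.6, seed = 10)
  d <- simulate_dataset(spec)
  cf <- fit_pls_cox(d, C = 1)
  direct <- fit_cox(survival_data(d$time, d$status, scale(d$covariates)))
  expect_equal(abs(unname(cf$survival_stage$beta)),
               abs(unname(direct$beta)), tolerance = 1e-6)
  # external oracle: coxph on the exported score matrix
  ref <- survival::coxph(survival::Surv(d$time, d$status) ~ dec,
                         data = list(dec = cf$decomposition$scores),
                         ties = "efron")
  expect_equal(unname(cf$survival_stage$beta), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("PLS composites survive strong collinearity with p >= n", {
  spec <- simulation_spec(n = 60, p = 80, corr_max = 0.9, seed = 11)
  d <- simulate_dataset(spec)
  for (C in c(1, 3, 5)) {
    cf <- fit_pls_spline(d, C = C, scale = "hazard", n_internal_knots = 0)
    expect_true(all(is.finite(cf$covariate_coefficients)))
    expect_true(is.finite(cf$survival_stage$aic))
  }
  expect_error(fit_rp(d, "hazard", 0), "refusing")
})

test_that("coefficient table covers every covariate on the requested scale", {
  spec <- simulation_spec(n = 80, p = 15, seed = 12)
  d <- simulate_dataset(spec)
  cf <- fit_pls_spline(d, C = 2, scale = "hazard", n_internal_knots = 0)
  tab <- covariate_coefficients(cf)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$covariate, paste0("x", 1:15))
  raw <- covariate_coefficients(cf, unstandardized = TRUE)
  expect_equal(raw$coefficient,
               tab$coefficient / cf$decomposition$scale_factors,
               ignore_attr = TRUE)
})
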