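#' Extract partial least squares latent components
#'
#' Univariate-response PLS regression by NIPALS with deflation of the
#' covariate matrix. Covariates are standardized to training mean 0 and
#' variance 1 before extraction, so components are well defined for
#' collinear designs and for p >= n. Each weight vector is sign-fixed so
#' its largest-magnitude entry is positive, making decompositions
#' reproducible across runs and platforms.
#'
#' @param X Numeric n x p covariate matrix.
#' @param response Numeric vector of length n (for the survival composition
#'   this is log observed time).
#' @param C Number of components, 1 <= C <= min(p, n-1) and at most the
#'   rank of the standardized design.
#' @return An object of class \code{pls_decomposition}: \code{n_components},
#'   \code{weights} (p x C), \code{loadings} (p x C), \code{scores}
#'   (n x C, mutually orthogonal), \code{y_loadings} (length C),
#'   \code{center}, \code{scale_factors}, \code{projection} (the p x C
#'   matrix \eqn{W(P'W)^{-1}} that maps standardized covariates to scores),
#'   and \code{covariate_names}.
#' @export
extract_components <- function(X, response, C) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  C <- as.integer(C)
  stopifnot(length(response) == n, all(is.finite(X)), all(is.finite(response)))
  if (C < 1 || C > min(p, n - 1))
    stop("'C' must satisfy 1 <= C <= min(p, n-1) = ", min(p, n - 1))
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  center <- colMeans(X)
  scale_factors <- apply(X, 2, stats::sd)
  bad <- which(scale_factors == 0 | !is.finite(scale_factors))
  if (length(bad))
    stop("zero-variance covariate(s): ", paste(cn[bad], collapse = ", "))
  Xs <- sweep(sweep(X, 2, center), 2, scale_factors, "/")
  y <- as.numeric(scale(response))

  W <- P <- matrix(0, p, C)
  Tm <- matrix(0, n, C)
  q <- numeric(C)
  Xd <- Xs
  for (c in seq_len(C)) {
    w <- drop(crossprod(Xd, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 * sqrt(n))
      stop("component ", c, " exceeds the effective rank of the design")
    w <- w / nw
    w <- w * sign(w[which.max(abs(w))])   # deterministic sign convention
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12)
      stop("component ", c, " exceeds the effective rank of the design")
    pp <- drop(crossprod(Xd, tt)) / t2
    q[c] <- sum(y * tt) / t2
    W[, c] <- w; P[, c] <- pp; Tm[, c] <- tt
    Xd <- Xd - tcrossprod(tt, pp)
  }
  projection <- W %*% solve(crossprod(P, W))
  dimnames(W) <- dimnames(P) <- list(cn, paste0("comp", seq_len(C)))
  dimnames(projection) <- dimnames(W)
  colnames(Tm) <- paste0("comp", seq_len(C))
  structure(list(n_components = C, weights = W, loadings = P, scores = Tm,
                 y_loadings = q, center = center,
                 scale_factors = scale_factors, projection = projection,
                 covariate_names = cn),
            class = "pls_decomposition")
}

#' Project new observations onto stored PLS components
#'
#' Applies the training centering and scaling, then the fixed projection
#' \eqn{W(P'W)^{-1}}. Projecting the training covariates reproduces the
#' stored scores.
#'
#' @param decomposition A \code{pls_decomposition}.
#' @param X_new Numeric m x p matrix with the same columns as the training
#'   covariates.
#' @return m x C score matrix.
#' @export
project <- function(decomposition, X_new) {
  stopifnot(inherits(decomposition, "pls_decomposition"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(decomposition$center))
    stop("X_new has ", ncol(X_new), " columns; decomposition expects ",
         length(decomposition$center))
  Xs <- sweep(sweep(X_new, 2, decomposition$center), 2,
              decomposition$scale_factors, "/")
  S <- Xs %*% decomposition$projection
  colnames(S) <- colnames(decomposition$scores)
  S
}

#' @export
print.pls_decomposition <- function(x, ...) {
  cat("PLS decomposition:", x$n_components, "component(s) from",
      length(x$center), "covariates,", nrow(x$scores), "training rows\n")
  invisible(x)
}

# shared composition stage: decompose on log observed time, build the
# score-predictor dataset used by both survival stages
.pls_stage <- function(data, C) {
  stopifnot(inherits(data, "survival_data"))
  if (ncol(data$covariates) < 1)
    stop("PLS stage requires at least one covariate")
  dec <- extract_components(data$covariates, log(data$time), C)
  sdata <- survival_data(data$time, data$status, dec$scores)
  list(decomposition = dec, score_data = sdata)
}

#' Fit the PLS-spline composite model
#'
#' Stage 1 extracts C latent components from the (standardized) covariates
#' with log observed time as the working response; stage 2 fits the
#' flexible parametric spline model of \code{\link{fit_rp}} with the score
#' matrix as predictors. Component coefficients are back-projected to
#' per-covariate coefficients (on the standardized covariate scale) via
#' \eqn{b = W(P'W)^{-1}\hat\beta}.
#'
#' @param data A \code{\link{survival_data}}.
#' @param C Number of latent components (default 2).
#' @param scale Modelling scale, see \code{\link{fit_rp}}.
#' @param n_internal_knots Number of internal spline knots.
#' @return An object of class \code{composite_fit} with elements
#'   \code{decomposition}, \code{survival_stage} (an \code{rp_fit}), and
#'   \code{covariate_coefficients} (length p, standardized scale).
#' @examples
#' d <- simulate_dataset(simulation_spec(n = 80, p = 30, seed = 7))
#' cf <- fit_pls_spline(d, C = 2, scale = "hazard", n_internal_knots = 0)
#' cf$survival_stage$aic
#' @export
fit_pls_spline <- function(data, C = 2L, scale = c("hazard", "odds", "normal"),
                           n_internal_knots = 0L) {
  st <- withCallingHandlers(
    .pls_stage(data, C),
    error = function(e) stop("PLS stage: ", conditionMessage(e), call. = FALSE))
  fit <- tryCatch(
    fit_rp(st$score_data, scale = scale, n_internal_knots = n_internal_knots),
    error = function(e) stop("survival stage: ", conditionMessage(e),
                             call. = FALSE))
  .composite(st$decomposition, fit, fit$beta)
}

#' Fit the PLS-Cox benchmark model
#'
#' Identical component extraction to \code{\link{fit_pls_spline}} (so model
#' comparisons isolate the survival stage), followed by a Cox
#' proportional hazards fit on the score matrix.
#'
#' @inheritParams fit_pls_spline
#' @return A \code{composite_fit} whose \code{survival_stage} is a
#'   \code{cox_fit}.
#' @export
fit_pls_cox <- function(data, C = 2L) {
  st <- withCallingHandlers(
    .pls_stage(data, C),
    error = function(e) stop("PLS stage: ", conditionMessage(e), call. = FALSE))
  fit <- tryCatch(
    fit_cox(st$score_data),
    error = function(e) stop("survival stage: ", conditionMessage(e),
                             call. = FALSE))
  .composite(st$decomposition, fit, fit$beta)
}

.composite <- function(decomposition, survival_stage, component_beta) {
  b <- drop(decomposition$projection %*% component_beta)
  names(b) <- decomposition$covariate_names
  structure(list(decomposition = decomposition,
                 survival_stage = survival_stage,
                 covariate_coefficients = b),
            class = "composite_fit")
}

#' @export
print.composite_fit <- function(x, ...) {
  kind <- if (inherits(x$survival_stage, "rp_fit")) "PLS-spline" else "PLS-Cox"
  cat(kind, "composite fit,", x$decomposition$n_components, "component(s)\n")
  print(x$survival_stage)
  invisible(x)
}

#' Covariate-level coefficient table of a composite fit
#'
#' @param fit A \code{composite_fit}.
#' @param unstandardized If \code{TRUE}, rescale coefficients to the
#'   original covariate units (divide by each covariate's training standard
#'   deviation). Default reports on the standardized scale.
#' @return Data frame with columns \code{covariate} and \code{coefficient}.
#' @export
covariate_coefficients <- function(fit, unstandardized = FALSE) {
  stopifnot(inherits(fit, "composite_fit"))
  b <- fit$covariate_coefficients
  if (unstandardized) b <- b / fit$decomposition$scale_factors
  data.frame(covariate = names(b), coefficient = unname(b))
}
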