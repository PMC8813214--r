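#' Place knots for a restricted cubic spline in log time
#'
#' Boundary knots are placed at the minimum and maximum of the uncensored
#' log event times; internal knots at equally spaced centiles of the same
#' values (one internal knot sits at the median, two at the 33rd/67th
#' centiles, and so on). Censored observations never influence knot
#' placement.
#'
#' @param log_event_times Numeric vector of log event times from uncensored
#'   subjects only. Must contain at least two distinct values.
#' @param n_internal Number of internal knots (nonnegative integer).
#' @return An object of class \code{knot_vector}: a list with elements
#'   \code{boundary_low}, \code{boundary_high} and \code{internal} (a
#'   possibly empty increasing numeric vector), all on the log-time scale.
#' @examples
#' place_knots(log(c(1, 2, 3, 4, 5)), n_internal = 1)
#' @export
place_knots <- function(log_event_times, n_internal = 0L) {
  stopifnot(is.numeric(log_event_times), length(log_event_times) > 0,
            all(is.finite(log_event_times)))
  n_internal <- as.integer(n_internal)
  if (n_internal < 0L) stop("'n_internal' must be nonnegative")
  if (length(unique(log_event_times)) < 2L)
    stop("fewer than 2 distinct uncensored log event times: ",
         "data are degenerate, cannot place boundary knots")
  lo <- min(log_event_times)
  hi <- max(log_event_times)
  internal <- numeric(0)
  if (n_internal > 0L) {
    probs <- seq_len(n_internal) / (n_internal + 1)
    internal <- unname(stats::quantile(log_event_times, probs = probs))
    knots <- c(lo, internal, hi)
    if (anyDuplicated(knots) || is.unsorted(knots, strictly = TRUE))
      stop("centile-based internal knots collide with each other or with ",
           "a boundary knot; reduce 'n_internal'")
  }
  structure(list(boundary_low = lo, boundary_high = hi, internal = internal),
            class = "knot_vector")
}

#' Construct a restricted cubic spline basis
#'
#' Packages a knot vector as a spline basis with \code{n_basis} derived
#' variables (excluding the intercept): the linear log-time term plus one
#' Royston-Parmar derived variable per internal knot.
#'
#' @param knots A \code{knot_vector} from \code{\link{place_knots}}.
#' @return An object of class \code{spline_basis}.
#' @export
spline_basis <- function(knots) {
  stopifnot(inherits(knots, "knot_vector"))
  structure(list(knots = knots, n_basis = 1L + length(knots$internal)),
            class = "spline_basis")
}

# (x)+^3 and its derivative, vectorized
.plus3 <- function(x) ifelse(x > 0, x^3, 0)
.plus3_d <- function(x) ifelse(x > 0, 3 * x^2, 0)

#' Evaluate the restricted cubic spline basis
#'
#' Column 1 is log time itself; column \eqn{j+1} is the Royston-Parmar
#' derived variable for internal knot \eqn{k_j}:
#' \deqn{v_j(x) = (x-k_j)_+^3 - \lambda_j (x-k_{min})_+^3 -
#'   (1-\lambda_j)(x-k_{max})_+^3,\quad
#'   \lambda_j = (k_{max}-k_j)/(k_{max}-k_{min}),}
#' which is twice continuously differentiable everywhere and exactly linear
#' beyond both boundary knots, so extrapolation outside the observed
#' follow-up uses the linear tails.
#'
#' @param log_t Numeric vector of evaluation points (log time).
#' @param basis A \code{spline_basis}.
#' @return Numeric matrix with \code{length(log_t)} rows and
#'   \code{basis$n_basis} columns.
#' @export
evaluate_basis <- function(log_t, basis) {
  stopifnot(inherits(basis, "spline_basis"), is.numeric(log_t))
  kv <- basis$knots
  out <- matrix(0, length(log_t), basis$n_basis)
  out[, 1L] <- log_t
  if (length(kv$internal)) {
    kmin <- kv$boundary_low
    kmax <- kv$boundary_high
    for (j in seq_along(kv$internal)) {
      kj <- kv$internal[j]
      lam <- (kmax - kj) / (kmax - kmin)
      out[, j + 1L] <- .plus3(log_t - kj) - lam * .plus3(log_t - kmin) -
        (1 - lam) * .plus3(log_t - kmax)
    }
  }
  out
}

#' Analytic derivative of the spline basis with respect to log time
#'
#' Needed for the event part of the flexible parametric likelihood, where
#' the hazard involves \eqn{d\eta / d\ln t}. Column 1 is identically 1.
#'
#' @inheritParams evaluate_basis
#' @return Numeric matrix, same shape as \code{\link{evaluate_basis}}.
#' @export
evaluate_basis_derivative <- function(log_t, basis) {
  stopifnot(inherits(basis, "spline_basis"), is.numeric(log_t))
  kv <- basis$knots
  out <- matrix(0, length(log_t), basis$n_basis)
  out[, 1L] <- 1
  if (length(kv$internal)) {
    kmin <- kv$boundary_low
    kmax <- kv$boundary_high
    for (j in seq_along(kv$internal)) {
      kj <- kv$internal[j]
      lam <- (kmax - kj) / (kmax - kmin)
      out[, j + 1L] <- .plus3_d(log_t - kj) - lam * .plus3_d(log_t - kmin) -
        (1 - lam) * .plus3_d(log_t - kmax)
    }
  }
  out
}

#' @export
print.knot_vector <- function(x, ...) {
  cat("Knot vector (log-time scale)\n")
  cat("  boundaries:", format(x$boundary_low), "--", format(x$boundary_high), "\n")
  if (length(x$internal))
    cat("  internal:  ", paste(format(x$internal), collapse = ", "), "\n")
  else cat("  internal:   none\n")
  invisible(x)
}
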