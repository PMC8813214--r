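#' Construct a survival dataset
#'
#' One row per subject: a positive follow-up time, a 0/1 event status
#' (1 = event observed, 0 = censored), and a numeric covariate matrix.
#'
#' @param time Vector of positive follow-up times.
#' @param status 0/1 vector, same length.
#' @param covariates Numeric matrix (or data frame) with one row per
#'   subject; may have zero columns for covariate-free data.
#' @param covariate_names Optional column names; defaults to existing names
#'   or \code{x1..xp}.
#' @return An object of class \code{survival_data}.
#' @export
survival_data <- function(time, status, covariates = NULL,
                          covariate_names = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (length(status) != n || nrow(covariates) != n)
    stop("'time', 'status' and 'covariates' must describe the same subjects")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all follow-up times must be positive and finite")
  if (!all(status %in% c(0, 1)))
    stop("'status' must be coded 0 (censored) / 1 (event)")
  if (ncol(covariates) > 0 && any(!is.finite(covariates)))
    stop("covariate matrix contains non-finite values")
  if (is.null(covariate_names)) {
    covariate_names <- colnames(covariates)
    if (is.null(covariate_names) && ncol(covariates) > 0)
      covariate_names <- paste0("x", seq_len(ncol(covariates)))
  }
  colnames(covariates) <- covariate_names
  structure(list(time = time, status = status, covariates = covariates,
                 covariate_names = covariate_names),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat("Survival data:", length(x$time), "subjects,",
      sum(x$status), "events,", ncol(x$covariates), "covariates\n")
  invisible(x)
}

#' Subset a survival dataset by row
#' @param data A \code{survival_data} object.
#' @param idx Integer or logical row index.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "survival_data"))
  survival_data(data$time[idx], data$status[idx],
                data$covariates[idx, , drop = FALSE],
                data$covariate_names)
}

#' Read survival data from delimited text
#'
#' Expects a header with columns \code{time}, \code{status}, then covariate
#' columns.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @export
read_survival_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!all(c("time", "status") %in% names(df)))
    stop("file must contain 'time' and 'status' columns")
  covs <- df[, setdiff(names(df), c("time", "status")), drop = FALSE]
  survival_data(df$time, df$status, as.matrix(covs))
}

#' Write survival data to delimited text
#' @param data A \code{survival_data} object.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @export
write_survival_csv <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "survival_data"))
  df <- data.frame(time = data$time, status = data$status,
                   check.names = FALSE)
  if (ncol(data$covariates) > 0)
    df <- cbind(df, as.data.frame(data$covariates))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
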