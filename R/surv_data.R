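#' Right-censored survival dataset
#'
#' Bundles observed follow-up times, event indicators and a numeric
#' covariate matrix into a validated container used by all fitting,
#' prediction and importance functions in the package. Follow-up time
#' is the minimum of the true event time and the censoring time; the
#' status indicator is 1 when the event was observed and 0 when the
#' subject was censored.
#'
#' @param time numeric vector of strictly positive follow-up times.
#' @param status integer/numeric vector of event indicators, 1 = event
#'   observed, 0 = right-censored.
#' @param x numeric matrix or data frame of covariates, one row per
#'   subject; no missing values.
#' @param names optional character vector of covariate names; defaults
#'   to the column names of `x` (or `x1..xp`).
#'
#' @return An object of class `surv_data` with components `time`,
#'   `status`, `x` (numeric matrix) and `names`.
#' @examples
#' d <- surv_data(c(2, 5, 3), c(1, 0, 1), cbind(a = 1:3, b = c(0, 1, 0)))
#' d$names
#' @export
surv_data <- function(time, status, x, names = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = length(time))
  storage.mode(x) <- "double"
  if (is.null(names)) {
    names <- colnames(x)
    if (is.null(names)) names <- paste0("x", seq_len(ncol(x)))
  }
  colnames(x) <- names
  obj <- structure(
    list(time = time, status = status, x = x, names = names),
    class = "surv_data"
  )
  validate_surv_data(obj)
  obj
}

validate_surv_data <- function(d) {
  n <- length(d$time)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (length(d$status) != n || nrow(d$x) != n) {
    stop("time, status and covariate rows must have equal length", call. = FALSE)
  }
  if (anyNA(d$time) || any(d$time <= 0)) {
    stop("all follow-up times must be strictly positive", call. = FALSE)
  }
  if (anyNA(d$status) || !all(d$status %in% c(0, 1))) {
    stop("status must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  if (anyNA(d$x)) stop("covariates must not contain missing values", call. = FALSE)
  if (sum(d$status) < 1) stop("need at least one observed event", call. = FALSE)
  if (length(d$names) != ncol(d$x)) {
    stop("covariate names do not match covariate columns", call. = FALSE)
  }
  invisible(d)
}

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf(
    "<surv_data> %d subjects, %d covariates, %d events (%.2f%% censored)\n",
    length(x$time), ncol(x$x), sum(x$status),
    100 * mean(x$status == 0)
  ))
  invisible(x)
}

#' Number of subjects and covariates
#' @param x a `surv_data` object.
#' @param ... unused.
#' @return `dim` returns `c(n, p)`.
#' @export
dim.surv_data <- function(x) c(length(x$time), ncol(x$x))

#' Summarize a survival dataset
#'
#' One-row summary in the conventional benchmark-table layout: sample
#' size, covariate count, censored count and the censoring rate as a
#' percentage rounded to two decimals.
#'
#' @param object a `surv_data` object.
#' @param ... unused.
#' @return A one-row data frame with columns `n`, `p`, `events`,
#'   `censored`, `censoring_rate` (percent, 2 decimals).
#' @examples
#' d <- surv_data(1:10, rep(c(1, 0), 5), matrix(rnorm(20), 10))
#' summary(d)
#' @export
summary.surv_data <- function(object, ...) {
  n <- length(object$time)
  censored <- sum(object$status == 0)
  data.frame(
    n = n,
    p = ncol(object$x),
    events = n - censored,
    censored = censored,
    censoring_rate = round(100 * censored / n, 2)
  )
}

#' Read / write survival datasets as CSV
#'
#' The package's CSV dialect has a header row with a follow-up time
#' column, a 0/1 status column (1 = event) and one numeric column per
#' covariate. Other layouts are accommodated through the column-name
#' arguments.
#'
#' @param path file path.
#' @param time_col,status_col names of the time and status columns
#'   (defaults `"time"`, `"status"`).
#' @return `read_surv_csv` returns a `surv_data`; `write_surv_csv`
#'   invisibly returns `path`.
#' @examples
#' d <- surv_data(c(1, 2, 4), c(1, 1, 0), cbind(z = c(0.5, -1, 2)))
#' f <- tempfile(fileext = ".csv")
#' write_surv_csv(d, f)
#' read_surv_csv(f)
#' @export
read_surv_csv <- function(path, time_col = "time", status_col = "status") {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c(time_col, status_col), names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  covs <- setdiff(names(df), c(time_col, status_col))
  if (!length(covs)) stop("no covariate columns found", call. = FALSE)
  surv_data(df[[time_col]], df[[status_col]], df[covs], names = covs)
}

#' @param data a `surv_data` object.
#' @rdname read_surv_csv
#' @export
write_surv_csv <- function(data, path) {
  stopifnot(inherits(data, "surv_data"))
  df <- data.frame(time = data$time, status = data$status,
                   data$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
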