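#' Time-course container
#'
#' Holds strictly positive concentration values indexed by condition, variable
#' and sampling time. Values are stored as a 3-dimensional array with
#' dimensions (variable, time, condition); sampling times must be strictly
#' increasing with at least two points. Strict positivity is required because
#' relative-error objectives divide by observed values.
#'
#' @param values Numeric array `n_var x n_time x n_cond`, or a `n_var x n_time`
#'   matrix for a single condition.
#' @param times Strictly increasing numeric vector of sampling times (weeks).
#' @param variables Character vector of variable names.
#' @param conditions Character vector of condition labels (default `"cond1"`).
#' @return An object of class `"ss_timecourse"`.
#' @seealso [read_timecourse()], [as.data.frame.ss_timecourse()]
#' @export
ss_timecourse <- function(values, times, variables = NULL, conditions = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3)
  d <- dim(values)
  times <- as.numeric(times)
  if (length(times) != d[2] || length(times) < 2 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing, length >= 2, matching dim 2 of values")
  }
  if (is.null(variables)) variables <- paste0("X", seq_len(d[1]))
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(d[3]))
  stopifnot(length(variables) == d[1], length(conditions) == d[3])
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("time-course values must be finite and strictly positive")
  }
  dimnames(values) <- list(variables, format(times, trim = TRUE), conditions)
  structure(list(values = values, times = times,
                 variables = variables, conditions = conditions),
            class = "ss_timecourse")
}

#' @export
print.ss_timecourse <- function(x, ...) {
  cat("Time-course set:", length(x$variables), "variables x",
      length(x$times), "times x", length(x$conditions), "condition(s)\n")
  cat("Variables:", paste(x$variables, collapse = ", "), "\n")
  cat("Times:", x$times[1], "...", x$times[length(x$times)], "\n")
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a time course to long-format data frame
#'
#' @param x An [ss_timecourse()].
#' @param ... Unused.
#' @return A data frame with columns `condition`, `time`, `variable`, `value`.
#' @export
as.data.frame.ss_timecourse <- function(x, ...) {
  grid <- expand.grid(variable = x$variables, time = x$times,
                      condition = x$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(condition = grid$condition, time = grid$time,
                    variable = grid$variable, value = as.vector(x$values),
                    stringsAsFactors = FALSE)
  out[order(out$condition, out$time, out$variable), , drop = FALSE]
}

#' Read or write time courses as long-format CSV
#'
#' The delimited format has the header `condition,time,variable,value`, one row
#' per observation. All (condition, variable) series must share the same
#' sampling-time grid.
#'
#' @param path CSV file path.
#' @return `read_timecourse()` returns an [ss_timecourse()];
#'   `write_timecourse()` returns `path` invisibly.
#' @export
read_timecourse <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time", "variable", "value")
  if (!all(need %in% names(df))) {
    stop("time-course CSV must have columns: ", paste(need, collapse = ", "))
  }
  conditions <- unique(df$condition)
  variables <- unique(df$variable)
  times <- sort(unique(df$time))
  arr <- array(NA_real_, c(length(variables), length(times), length(conditions)))
  ci <- match(df$condition, conditions)
  vi <- match(df$variable, variables)
  ti <- match(df$time, times)
  arr[cbind(vi, ti, ci)] <- df$value
  if (anyNA(arr)) stop("incomplete time-course grid: every (condition, variable, time) cell is required")
  ss_timecourse(arr, times, variables, conditions)
}

#' @rdname read_timecourse
#' @param tc An [ss_timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "ss_timecourse"))
  write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: check two time courses share the same index sets.
check_same_index <- function(a, b) {
  if (!identical(a$variables, b$variables) ||
      !identical(a$conditions, b$conditions) ||
      length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9) {
    stop("time-course index sets (conditions, variables, times) do not match")
  }
  invisible(TRUE)
}
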