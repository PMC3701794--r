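#' Average relative error between calculated and observed time courses
#'
#' The fitting objective: for one condition,
#' \deqn{E = \frac{100}{N\,T} \sum_{i=1}^{N} \sum_{t=1}^{T}
#'   \left| \frac{X_{i,cal,t} - X_{i,exp,t}}{X_{i,exp,t}} \right|}
#' i.e. the average absolute relative error per sampling point, reported in
#' percent (`N` variables, `T` sampling times). Multi-condition input averages
#' the per-condition errors. With `squared = TRUE` the relative deviations are
#' squared instead of taken in absolute value (an alternative objective; the
#' default is the absolute form).
#'
#' @param calculated,observed [ss_timecourse()] objects with identical index
#'   sets; `observed` strictly positive (enforced by the container).
#' @param squared Use squared relative deviations instead of absolute values.
#' @return An object of class `"ssys_fitscore"`: a list with
#'   `total_error_percent`, `per_variable_error` (averaged over conditions and
#'   times, in percent), and `failed` (always `FALSE` here).
#' @examples
#' obs <- ss_timecourse(matrix(c(1, 2), 1), times = c(0, 1))
#' cal <- ss_timecourse(matrix(c(1.1, 1.8), 1), times = c(0, 1))
#' average_relative_error(cal, obs)$total_error_percent  # 10
#' @export
average_relative_error <- function(calculated, observed, squared = FALSE) {
  stopifnot(inherits(calculated, "ss_timecourse"),
            inherits(observed, "ss_timecourse"))
  check_same_index(calculated, observed)
  rel <- (calculated$values - observed$values) / observed$values
  rel <- if (squared) rel^2 else abs(rel)
  # mean over variables and times within each condition, then over conditions
  per_cond <- apply(rel, 3, mean)
  per_var <- apply(rel, 1, mean)
  fitscore(total = 100 * mean(per_cond),
           per_variable = setNames(100 * per_var, observed$variables),
           failed = FALSE)
}

fitscore <- function(total, per_variable = NULL, failed = FALSE) {
  structure(list(total_error_percent = total,
                 per_variable_error = per_variable,
                 failed = failed),
            class = "ssys_fitscore")
}

#' @export
print.ssys_fitscore <- function(x, ...) {
  if (x$failed) {
    cat("Fit score: integration FAILED (penalty error",
        format(x$total_error_percent), "%)\n")
  } else {
    cat("Average relative error per sampling point:",
        format(x$total_error_percent, digits = 4), "%\n")
  }
  invisible(x)
}

#' Score a candidate S-system model against observed data
#'
#' Integrates `model` at the observed sampling times for each condition and
#' applies [average_relative_error()]. A failed integration (divergent or
#' non-finite trajectory) yields `failed = TRUE` with a large penalty error so
#' that selection among candidates remains totally ordered.
#'
#' @param model An [ssys_model()].
#' @param observed An [ss_timecourse()].
#' @param x0 Either `"first-observation"` (default: initialize each condition
#'   at its first observed point) or a positive numeric vector of length `n`.
#' @param penalty Error (in percent) assigned when integration fails.
#' @param squared Passed to [average_relative_error()].
#' @param ... Further arguments for [ssys_integrate()].
#' @return An `"ssys_fitscore"`.
#' @export
evaluate_candidate <- function(model, observed, x0 = "first-observation",
                               penalty = 1e6, squared = FALSE, ...) {
  stopifnot(inherits(model, "ssys_model"), inherits(observed, "ss_timecourse"))
  if (!identical(length(model$variables), length(observed$variables))) {
    stop("model and data dimension mismatch")
  }
  cal <- try(simulate_conditions(model, observed, x0, ...), silent = TRUE)
  if (inherits(cal, "try-error")) {
    return(fitscore(total = penalty, failed = TRUE))
  }
  average_relative_error(cal, observed, squared = squared)
}

# Integrate the model at the observed grid for every condition.
simulate_conditions <- function(model, observed, x0 = "first-observation", ...) {
  n <- length(model$variables)
  vals <- array(NA_real_, dim = dim(observed$values))
  for (d in seq_along(observed$conditions)) {
    start <- if (identical(x0, "first-observation")) {
      observed$values[, 1, d]
    } else {
      as.numeric(x0)
    }
    tc <- ssys_integrate(model, start, observed$times, ...)
    vals[, , d] <- tc$values[, , 1]
  }
  # positional correspondence between model and data variables is the contract
  ss_timecourse(vals, observed$times, observed$variables, observed$conditions)
}
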