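#' @export
print.ssys_fit <- function(x, ...) {
  cat("S-system network fit (", length(x$model$variables), " variables, ",
      x$control$trials, " trial(s), profile '", x$control$profile, "')\n",
      sep = "")
  cat("Selected trial:", x$best_trial, "\n")
  cat("Average relative error per sampling point:",
      format(x$score$total_error_percent, digits = 4), "%\n")
  invisible(x)
}

#' @export
summary.ssys_fit <- function(object, ...) {
  errs <- vapply(object$per_trial, `[[`, numeric(1), "error")
  structure(list(fit = object, trial_errors = errs,
                 n_free = count_free_parameters(object$model)),
            class = "summary.ssys_fit")
}

#' @export
print.summary.ssys_fit <- function(x, ...) {
  print(x$fit)
  cat("Free parameters:", x$n_free, "\n")
  cat("Per-trial best errors (%):\n")
  print(round(x$trial_errors, 4))
  cat("Per-variable error (%):\n")
  print(round(x$fit$score$per_variable_error, 4))
  cat("Selected model coefficients:\n")
  print(round(coef(x$fit), 4))
  invisible(x)
}

#' @export
coef.ssys_fit <- function(object, ...) coef(object$model)

#' @export
fitted.ssys_fit <- function(object, ...) {
  simulate_conditions(object$model, object$observed, object$x0)
}

#' @export
residuals.ssys_fit <- function(object, type = c("relative", "raw"), ...) {
  type <- match.arg(type)
  cal <- fitted(object)
  res <- cal$values - object$observed$values
  if (type == "relative") res <- res / object$observed$values
  res
}

#' Predict S-system trajectories at new times
#'
#' @param object An [ssys_fit()].
#' @param times Strictly increasing time vector (defaults to the observed
#'   grid).
#' @param x0 Initial state (defaults to the fit's initial-state policy applied
#'   to the first condition).
#' @param ... Passed to [ssys_integrate()].
#' @return An [ss_timecourse()].
#' @export
predict.ssys_fit <- function(object, times = NULL, x0 = NULL, ...) {
  times <- times %||% object$observed$times
  if (is.null(x0)) {
    x0 <- if (identical(object$x0, "first-observation")) {
      object$observed$values[, 1, 1]
    } else {
      object$x0
    }
  }
  ssys_integrate(object$model, x0, times, ...)
}

#' Plot observed points and fitted trajectories
#'
#' @param x An [ssys_fit()].
#' @param condition Condition to display (index or label).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ssys_fit <- function(x, condition = 1, ...) {
  obs <- x$observed
  if (is.character(condition)) condition <- match(condition, obs$conditions)
  cal <- fitted(x)
  nvar <- length(obs$variables)
  cols <- seq_len(nvar)
  dense <- seq(min(obs$times), max(obs$times), length.out = 200)
  smooth <- ssys_integrate(x$model, obs$values[, 1, condition], dense)
  matplot(dense, t(smooth$values[, , 1]), type = "l", lty = 1, col = cols,
          xlab = "time (weeks)", ylab = "concentration (normalized)",
          main = obs$conditions[condition], ...)
  matpoints(obs$times, t(obs$values[, , condition]), pch = 1, col = cols)
  legend("topright", legend = obs$variables, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate noisy datasets from a fitted model
#'
#' Draws replicate datasets from the fitted S-system trajectory with
#' multiplicative measurement noise, via [generate_dataset()].
#'
#' @param object An [ssys_fit()].
#' @param nsim Number of replicate datasets.
#' @param seed Seed for reproducibility.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param ... Passed to [generate_dataset()].
#' @return A list of `nsim` [ss_timecourse()] objects.
#' @export
simulate.ssys_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1007, ...) {
  if (!is.null(seed)) set.seed(seed)
  obs <- object$observed
  x0 <- if (identical(object$x0, "first-observation")) {
    obs$values[, 1, 1]
  } else {
    object$x0
  }
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seeds, function(s) {
    generate_dataset(object$model, x0, obs$times,
                     noise = noise_spec(cv = cv, seed = s), ...)
  })
}
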