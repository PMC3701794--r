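#' Integrate an S-system model forward in time
#'
#' Solves the S-system ordinary differential equations with `deSolve`'s
#' stiff-capable adaptive solver (`lsodar`) and a compiled right-hand side.
#' States are clamped at a positivity floor before exponentiation (real-valued
#' exponents are undefined on non-positive bases), and integration terminates
#' with an error as soon as any state exceeds the divergence ceiling — a guard
#' needed because candidate models proposed by the genetic algorithm can be
#' explosive.
#'
#' @param model An [ssys_model()].
#' @param x0 Strictly positive numeric vector of initial concentrations, taken
#'   as the state at `times[1]`.
#' @param times Strictly increasing numeric vector of at least two output times
#'   (weeks).
#' @param condition Condition label for the returned time course.
#' @param floor Positivity floor applied to states inside the right-hand side.
#' @param ceiling Divergence guard; any state exceeding it aborts integration.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param maxsteps Maximum internal solver steps per output interval.
#' @return An [ss_timecourse()] with one condition; the first column equals
#'   `x0` exactly.
#' @examples
#' decay <- ssys_model(alpha = 0, beta = 1, g = matrix(0), h = matrix(1))
#' tc <- ssys_integrate(decay, x0 = 2, times = 0:5)
#' tc$values[1, , 1]  # 2 * exp(-t)
#' @export
ssys_integrate <- function(model, x0, times, condition = "cond1",
                           floor = 1e-9, ceiling = 1e6,
                           rtol = 1e-8, atol = 1e-10, maxsteps = 10000L) {
  stopifnot(inherits(model, "ssys_model"))
  n <- length(model$variables)
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 must have length ", n)
  if (any(!is.finite(x0)) || any(x0 <= 0)) stop("x0 must be strictly positive")
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing with at least two points")
  }
  parms <- pad_parms(c(n, floor, ceiling, unname(model$alpha),
                       unname(model$beta), as.vector(model$g),
                       as.vector(model$h)))
  out <- quiet_stdout(try(suppressWarnings(
    deSolve::lsodar(y = x0, times = times, func = "ssys_deriv", parms = parms,
                    dllname = "ssysnet", initfunc = "ssys_init",
                    rootfunc = "ssys_root", nroot = 1L,
                    rtol = rtol, atol = atol, maxsteps = maxsteps)
  ), silent = TRUE))
  if (inherits(out, "try-error")) {
    stop_divergence(times[1], "solver failure")
  }
  out <- unclass(out)
  if (nrow(out) < length(times) || anyNA(out) || any(!is.finite(out))) {
    t_fail <- if (nrow(out) >= 1) out[nrow(out), 1] else times[1]
    stop_divergence(t_fail, "state exceeded ceiling or solver stopped early")
  }
  values <- t(out[, -1, drop = FALSE])
  values[, 1] <- x0  # first reported state is the initial condition, exactly
  values[values < floor] <- floor
  ss_timecourse(values, times, model$variables, condition)
}

# Divert stdout while the Fortran solver runs: pathological candidate models
# make DLSODAR print step-size warnings directly to the console.
quiet_stdout <- function(expr) {
  zz <- file(nullfile(), open = "wt")
  sink(zz)
  on.exit({ sink(); close(zz) }, add = TRUE)
  expr
}

# The compiled right-hand side takes a fixed-length parameter vector
# (supporting up to 16 state variables); pad with zeros.
SSYS_PARMS_LEN <- 3L + 2L * 16L + 2L * 16L * 16L

pad_parms <- function(p) {
  if (length(p) > SSYS_PARMS_LEN) {
    stop("model too large for the compiled solver (max 16 variables)")
  }
  c(p, numeric(SSYS_PARMS_LEN - length(p)))
}

stop_divergence <- function(time, msg) {
  cond <- structure(
    class = c("ssys_divergence_error", "error", "condition"),
    list(message = paste0("non-finite trajectory: ", msg,
                          " (t = ", format(time), ")"),
         call = sys.call(-1), time = time))
  stop(cond)
}

#' Steady state of an S-system model
#'
#' At steady state \eqn{\alpha_i \prod_j X_j^{g_{ij}} = \beta_i \prod_j
#' X_j^{h_{ij}}}; taking logarithms makes the condition linear in
#' \eqn{y_j = \log X_j}: \eqn{(G - H) y = \log(\beta/\alpha)}. This is the
#' classical property that the steady state of an S-system is computable with
#' linear algebra alone.
#'
#' @param model An [ssys_model()] with all `beta > 0`.
#' @param tol Reciprocal-condition-number threshold below which the exponent
#'   matrix is treated as singular.
#' @return Named positive numeric vector `X*`, or `NULL` if the exponent
#'   matrix `g - h` is singular (no unique positive steady state).
#' @examples
#' m <- ssys_model(alpha = 2, beta = 1, g = matrix(0), h = matrix(1))
#' steady_state(m)  # 2
#' @export
steady_state <- function(model, tol = 1e-10) {
  stopifnot(inherits(model, "ssys_model"))
  if (any(model$beta <= 0)) stop("steady_state requires all beta > 0")
  if (any(model$alpha <= 0)) {
    stop("alpha = 0 with beta > 0 admits no positive steady state")
  }
  A <- model$g - model$h
  b <- log(model$beta / model$alpha)
  if (rcond(A) < tol) return(NULL)
  y <- solve(A, b)
  setNames(exp(y), model$variables)
}
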