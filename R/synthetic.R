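#' Multiplicative measurement-noise specification
#'
#' Describes per-point multiplicative noise at a given coefficient of
#' variation (Cv). The default Cv of 0.1007 matches the analytical error of
#' the plasma amino-acid quantification the package's fixtures derive from.
#' The lognormal kind draws factors \eqn{\exp(N(-\sigma^2/2, \sigma^2))} with
#' \eqn{\sigma^2 = \log(1 + Cv^2)}, so the factor has mean 1 and coefficient
#' of variation exactly `cv`, and the noisy values stay strictly positive.
#' The normal kind draws factors \eqn{N(1, Cv^2)}, clamped to a small positive
#' floor.
#'
#' @param cv Coefficient of variation (fraction; default 0.1007).
#' @param kind `"lognormal"` (default) or `"normal"`.
#' @param seed Optional seed applied when the noise is drawn.
#' @return A list of class `"ssys_noise"`.
#' @export
noise_spec <- function(cv = 0.1007, kind = c("lognormal", "normal"),
                       seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(cv >= 0)
  structure(list(cv = cv, kind = kind, seed = seed), class = "ssys_noise")
}

#' Load a packaged fixture network model
#'
#' Returns one of the two packaged 5-variable plasma amino-acid S-system
#' models (Val, Leu, Ile, Ala, Gly): the healthy-control network
#' (`"Ins2+/+"`) or the hyperglycemic network (`"Ins2+/-"`), with the
#' published fitted parameter values. Masks are the estimation configuration
#' (full `g` free, diagonal-only `h`), under which each model has
#' \eqn{n(n+3) = 40} free parameters.
#'
#' @param condition `"Ins2+/+"` or `"Ins2+/-"` (a Unicode minus is accepted).
#' @return An [ssys_model()].
#' @examples
#' m <- load_fixture_model("Ins2+/+")
#' m$alpha
#' @export
load_fixture_model <- function(condition = c("Ins2+/+", "Ins2+/-")) {
  condition <- gsub("−", "-", condition[1])
  condition <- match.arg(condition, c("Ins2+/+", "Ins2+/-"))
  file <- if (condition == "Ins2+/+") "model_ins2_wt.json" else "model_ins2_het.json"
  read_ssys_model(system.file("extdata", file, package = "ssysnet",
                              mustWork = TRUE))
}

#' Load the packaged blood-sugar correlation table
#'
#' The packaged fixture table of Pearson correlation coefficients (and raw
#' two-sided p-values) between blood sugar and each plasma amino acid, used by
#' the variable-selection step. Its top five variables by `|r|` are valine,
#' isoleucine, leucine, glycine and alanine.
#'
#' @return An `"ssys_corr_ranking"` (see [rank_by_correlation()]).
#' @export
load_fixture_correlations <- function() {
  path <- system.file("extdata", "bs_correlations.csv", package = "ssysnet",
                      mustWork = TRUE)
  corr_ranking(read.csv(path, stringsAsFactors = FALSE))
}

#' Generate a synthetic time-course dataset from an S-system model
#'
#' Integrates the model and applies per-point multiplicative measurement
#' noise, emulating weekly plasma sampling. With `cv = 0` the clean trajectory
#' is returned exactly. Fully reproducible when `noise$seed` is set.
#'
#' @param model An [ssys_model()].
#' @param x0 Positive initial state (state at `times[1]`).
#' @param times Sampling times (weeks); default weekly weeks 3–20.
#' @param noise A [noise_spec()].
#' @param condition Condition label for the dataset.
#' @param ... Passed to [ssys_integrate()].
#' @return An [ss_timecourse()].
#' @examples
#' m <- load_fixture_model("Ins2+/+")
#' tc <- generate_dataset(m, rep(1, 5), noise = noise_spec(seed = 7))
#' @export
generate_dataset <- function(model, x0, times = 3:20,
                             noise = noise_spec(), condition = "synthetic",
                             ...) {
  stopifnot(inherits(noise, "ssys_noise"))
  clean <- ssys_integrate(model, x0, times, condition = condition, ...)
  if (noise$cv == 0) return(clean)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  k <- length(clean$values)
  factors <- if (noise$kind == "lognormal") {
    sdlog <- sqrt(log(1 + noise$cv^2))
    rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(rnorm(k, 1, noise$cv), 1e-6)
  }
  vals <- clean$values * array(factors, dim = dim(clean$values))
  ss_timecourse(vals, clean$times, clean$variables, clean$conditions)
}

#' Construct a random parameter-recovery problem
#'
#' Draws a random sparse stable S-system (rates in (0, 9], exponents within
#' [-2.5, 2.6], diagonal `g` structurally zero, diagonal-only `h`) and its
#' clean trajectory from an all-ones initial state over the weekly grid.
#' Candidate draws whose trajectory diverges, leaves the plausible range, or
#' stays essentially flat (uninformative for fitting) are rejected and
#' redrawn, up to `max_tries`.
#'
#' @param n Number of variables (1–6).
#' @param sparsity Fraction of off-diagonal `g` entries fixed at zero.
#' @param seed Seed making the problem instance deterministic.
#' @param times Sampling grid (weeks).
#' @param max_tries Redraw cap; exhausted cap is an error.
#' @return A list with `model` (the generating [ssys_model()], masks encoding
#'   its zero pattern), `data` (the clean [ss_timecourse()]), and `x0`.
#' @examples
#' prob <- make_recovery_problem(n = 2, sparsity = 0, seed = 11)
#' prob$model
#' @export
make_recovery_problem <- function(n, sparsity = 0.5, seed = 1L,
                                  times = 3:20, max_tries = 50L) {
  stopifnot(n >= 1, n <= 6, sparsity >= 0, sparsity <= 1)
  set.seed(as.integer(seed))
  x0 <- rep(1, n)
  for (try_i in seq_len(max_tries)) {
    alpha <- runif(n, 0.5, 9)
    beta <- runif(n, 0.5, 9)
    h <- diag(runif(n, 0.5, 2.5), n)
    g <- matrix(0, n, n)
    off <- which(row(g) != col(g))
    live <- off[runif(length(off)) >= sparsity]
    g[live] <- sample(c(-1, 1), length(live), replace = TRUE) *
      runif(length(live), 0.3, 2.5)
    mask_g <- g == 0
    model <- ssys_model(alpha, beta, g, h, mask_g = mask_g)
    tc <- try(ssys_integrate(model, x0, times), silent = TRUE)
    if (inherits(tc, "try-error")) next
    v <- tc$values
    if (any(v > 1e4) || any(v < 1e-4)) next
    # informative: at least one variable moves by >= 5% over the course
    spread <- apply(v[, , 1, drop = FALSE], 1, function(z) max(z) / min(z))
    if (max(spread) < 1.05) next
    return(list(model = model, data = tc, x0 = x0))
  }
  stop("could not draw a bounded, informative S-system in ", max_tries,
       " tries")
}
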