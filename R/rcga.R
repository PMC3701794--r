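#' Control settings for the real-coded genetic algorithm
#'
#' @param population_size Individuals per trial (>= 4).
#' @param generations Generation-alternation steps per trial; each step
#'   replaces one two-parent family (minimal generation gap).
#' @param trials Independent GA runs; the least-error model across trials is
#'   selected.
#' @param children_per_step Children generated per family per step.
#' @param sigma_xi Spread of the UNDX component along the parent axis
#'   (standard deviation as a multiple of the parent distance).
#' @param sigma_eta Spread of the orthogonal UNDX components, as a multiple of
#'   the third parent's distance from the parent axis; default
#'   `0.35 / sqrt(n_params)`, resolved at fit time.
#' @param bounds_rate Search box for `alpha` and `beta`.
#' @param bounds_exponent Search box for the exponents `g` and `h`.
#' @param penalty Error (percent) assigned to candidates whose integration
#'   fails.
#' @param rtol,atol,maxsteps Solver settings used while scoring candidates
#'   (looser than the reporting tolerance, for speed; the selected model is
#'   rescored at the strict tolerance).
#' @param log_every Print best error every this many generations (0 = silent).
#' @param profile `"desk"` (100 / 2,000 / 3; the default) or `"paper"`
#'   (population 300, 50,000 generations, 50 trials — the full-scale protocol).
#'   Explicit arguments override the profile values.
#' @return A list of class `"ssys_control"`.
#' @export
ssys_control <- function(population_size = NULL, generations = NULL,
                         trials = NULL, children_per_step = 10L,
                         sigma_xi = 0.5, sigma_eta = NULL,
                         bounds_rate = c(0, 15), bounds_exponent = c(-3, 3),
                         penalty = 1e6, rtol = 1e-6, atol = 1e-8,
                         maxsteps = 5000L, log_every = 0L,
                         profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  prof <- switch(profile,
                 desk = list(population_size = 100L, generations = 2000L, trials = 3L),
                 paper = list(population_size = 300L, generations = 50000L, trials = 50L))
  out <- list(
    population_size = as.integer(population_size %||% prof$population_size),
    generations = as.integer(generations %||% prof$generations),
    trials = as.integer(trials %||% prof$trials),
    children_per_step = as.integer(children_per_step),
    sigma_xi = sigma_xi, sigma_eta = sigma_eta,
    bounds_rate = bounds_rate, bounds_exponent = bounds_exponent,
    penalty = penalty, rtol = rtol, atol = atol,
    maxsteps = as.integer(maxsteps), log_every = as.integer(log_every),
    profile = profile)
  stopifnot(out$population_size >= 4L, out$generations >= 1L, out$trials >= 1L,
            out$children_per_step >= 1L)
  class(out) <- "ssys_control"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unimodal normal distribution crossover (UNDX)
#'
#' Three-parent real-coded recombination: the child is sampled around the
#' midpoint of parents 1 and 2, with a normal component along the axis joining
#' them (s.d. `sigma_xi` times their distance) and independent normal
#' components orthogonal to that axis (s.d. `sigma_eta` times the distance of
#' parent 3 from the axis). The child is clipped to the box bounds.
#'
#' Degenerate geometry is handled explicitly: coincident parents 1 and 2
#' suppress the axis component; if parent 3 also carries no off-axis distance
#' the child is exactly the midpoint.
#'
#' @param parent1,parent2,parent3 Equal-length numeric genomes.
#' @param sigma_xi,sigma_eta Spread parameters (see [ssys_control()]).
#' @param lower,upper Box bounds (recycled scalars allowed).
#' @return A numeric child genome.
#' @export
undx_crossover <- function(parent1, parent2, parent3,
                           sigma_xi = 0.5,
                           sigma_eta = 0.35 / sqrt(length(parent1)),
                           lower = -Inf, upper = Inf) {
  k <- length(parent1)
  stopifnot(length(parent2) == k, length(parent3) == k)
  m <- (parent1 + parent2) / 2
  d <- parent2 - parent1
  dn <- sqrt(sum(d^2))
  if (dn > 0) {
    u <- d / dn
    # distance of parent3 from the line through parent1, parent2
    w <- parent3 - parent1
    w_perp <- w - sum(w * u) * u
    D <- sqrt(sum(w_perp^2))
    e <- rnorm(k, 0, 1) * sigma_eta * D
    e <- e - sum(e * u) * u                 # keep orthogonal to the axis
    child <- m + rnorm(1, 0, sigma_xi) * d + e
  } else {
    D <- sqrt(sum((parent3 - m)^2))
    child <- m + rnorm(k, 0, 1) * sigma_eta * D
  }
  pmin(pmax(child, lower), upper)
}

# Build the candidate scorer used in the GA inner loop: genome -> E (percent).
make_evaluator <- function(skel, observed, x0, control,
                           floor = 1e-9, ceiling = 1e6) {
  pack <- make_parms_packer(skel, floor, ceiling)
  times <- observed$times
  Tn <- length(times)
  ncond <- length(observed$conditions)
  x0s <- lapply(seq_len(ncond), function(d) {
    if (identical(x0, "first-observation")) observed$values[, 1, d]
    else as.numeric(x0)
  })
  obs <- lapply(seq_len(ncond), function(d) observed$values[, , d])
  rtol <- control$rtol; atol <- control$atol; maxsteps <- control$maxsteps
  penalty <- control$penalty
  function(values) {
    parms <- pack(values)
    e <- 0
    for (d in seq_len(ncond)) {
      out <- quiet_stdout(try(suppressWarnings(
        deSolve::lsodar(y = x0s[[d]], times = times, func = "ssys_deriv",
                        parms = parms, dllname = "ssysnet",
                        initfunc = "ssys_init", rootfunc = "ssys_root",
                        nroot = 1L, rtol = rtol, atol = atol,
                        maxsteps = maxsteps)), silent = TRUE))
      if (inherits(out, "try-error") || nrow(out) < Tn) return(penalty)
      cal <- t(out[, -1, drop = FALSE])
      if (anyNA(cal) || any(!is.finite(cal))) return(penalty)
      e <- e + mean(abs(cal - obs[[d]]) / obs[[d]])
    }
    100 * e / ncond
  }
}

#' One minimal-generation-gap (MGG) step
#'
#' Steady-state generation alternation: two parent slots are drawn at random;
#' `children_per_step` children are produced by [undx_crossover()] (each child
#' drawing a fresh third parent); the family (two parents plus children) is
#' evaluated and the two slots are refilled with the family's best individual
#' plus a rank-weighted roulette pick from the remainder. Population size is
#' conserved and the family best is never discarded, so the best error in the
#' population never increases.
#'
#' @param population List with elements `genomes` (matrix, one column per
#'   individual) and `errors` (numeric vector of their scores).
#' @param evaluate Function mapping a genome vector to its error.
#' @param control An [ssys_control()].
#' @param lower,upper Box bounds for [undx_crossover()].
#' @return The updated population list.
#' @export
mgg_step <- function(population, evaluate, control, lower, upper) {
  genomes <- population$genomes
  errors <- population$errors
  np <- ncol(genomes)
  sigma_eta <- control$sigma_eta %||% (0.35 / sqrt(nrow(genomes)))
  slots <- sample.int(np, 2L)
  p1 <- genomes[, slots[1]]
  p2 <- genomes[, slots[2]]
  nc <- control$children_per_step
  fam <- matrix(0, nrow(genomes), nc + 2L)
  fam[, 1] <- p1; fam[, 2] <- p2
  fam_err <- c(errors[slots[1]], errors[slots[2]], numeric(nc))
  for (ci in seq_len(nc)) {
    p3 <- genomes[, sample.int(np, 1L)]
    child <- undx_crossover(p1, p2, p3, control$sigma_xi, sigma_eta,
                            lower, upper)
    fam[, ci + 2L] <- child
    fam_err[ci + 2L] <- evaluate(child)
  }
  best <- which.min(fam_err)
  rest <- setdiff(seq_len(nc + 2L), best)
  # rank-weighted roulette on the remaining family (smaller error = higher rank)
  rk <- rank(fam_err[rest], ties.method = "first")
  wt <- (length(rest) - rk + 1)
  pick <- rest[sample.int(length(rest), 1L, prob = wt)]
  genomes[, slots[1]] <- fam[, best]
  errors[slots[1]] <- fam_err[best]
  genomes[, slots[2]] <- fam[, pick]
  errors[slots[2]] <- fam_err[pick]
  list(genomes = genomes, errors = errors)
}

#' Fit an S-system network model to observed time courses
#'
#' Infers the free parameters of an S-system (under the structural masks) from
#' observed time-course data by minimizing the average relative error per
#' sampling point ([average_relative_error()]) with a real-coded genetic
#' algorithm: UNDX crossover under a minimal-generation-gap alternation
#' scheme. `trials` independent runs are performed from distinct sub-seeds and
#' the least-error model across trials is selected.
#'
#' @param observed An [ss_timecourse()] (one or more conditions; a
#'   multi-condition fit averages per-condition errors).
#' @param mask_g,mask_h Logical structural masks (`TRUE` = coefficient fixed at
#'   zero); defaults: free `g`, diagonal-only `h`.
#' @param control An [ssys_control()].
#' @param seed Master seed; trial `k` runs from a sub-seed derived from it, so
#'   results are fully reproducible.
#' @param x0 `"first-observation"` or a positive numeric vector (initial state
#'   used when integrating candidates).
#' @return An object of class `"ssys_fit"` with components `model` (the
#'   selected [ssys_model()]), `score` (its error, rescored at the strict
#'   integration tolerance), `per_trial` (best genome and error per trial),
#'   `history` (per-generation best-so-far error trace per trial), plus the
#'   call ingredients. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' prob <- make_recovery_problem(n = 1, sparsity = 0, seed = 7)
#' fit <- ssys_fit(prob$data, mask_g = prob$model$mask_g,
#'                 mask_h = prob$model$mask_h,
#'                 control = ssys_control(population_size = 40,
#'                                        generations = 200, trials = 1),
#'                 seed = 1)
#' fit
#' }
#' @export
ssys_fit <- function(observed, mask_g = NULL, mask_h = NULL,
                     control = ssys_control(), seed = 1L,
                     x0 = "first-observation") {
  stopifnot(inherits(observed, "ss_timecourse"), inherits(control, "ssys_control"))
  skel <- ssys_skeleton(observed$variables, mask_g, mask_h)
  bounds <- genome_bounds(skel, control$bounds_rate, control$bounds_exponent)
  evaluate <- make_evaluator(skel, observed, x0, control)
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max - 1L, control$trials)

  per_trial <- vector("list", control$trials)
  history <- vector("list", control$trials)
  for (tr in seq_len(control$trials)) {
    set.seed(trial_seeds[tr])
    np <- control$population_size
    genomes <- matrix(runif(bounds$k * np, bounds$lower, bounds$upper),
                      nrow = bounds$k)
    errors <- apply(genomes, 2, evaluate)
    pop <- list(genomes = genomes, errors = errors)
    trace <- numeric(control$generations)
    for (gen in seq_len(control$generations)) {
      pop <- mgg_step(pop, evaluate, control, bounds$lower, bounds$upper)
      trace[gen] <- min(pop$errors)
      if (control$log_every > 0 && gen %% control$log_every == 0) {
        message(sprintf("trial %d gen %d best E = %.4f%%", tr, gen, trace[gen]))
      }
    }
    ib <- which.min(pop$errors)
    per_trial[[tr]] <- list(genome = pop$genomes[, ib],
                            error = pop$errors[ib], seed = trial_seeds[tr])
    history[[tr]] <- cummin(trace)
  }
  errs <- vapply(per_trial, `[[`, numeric(1), "error")
  if (all(errs >= control$penalty)) {
    stop("no feasible model: every trial's best candidate failed integration")
  }
  best_tr <- which.min(errs)
  model <- decode_genome(per_trial[[best_tr]]$genome, skel)
  score <- evaluate_candidate(model, observed, x0 = x0,
                              penalty = control$penalty)
  structure(list(model = model, score = score,
                 per_trial = per_trial, history = history,
                 best_trial = best_tr, control = control, seed = seed,
                 x0 = x0, observed = observed, skeleton = skel),
            class = "ssys_fit")
}
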