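#' Perturb one interrelated coefficient
#'
#' Returns a copy of the model with a single coefficient multiplied by
#' `1 + fraction` (a multiplicative perturbation, so sign is preserved and the
#' magnitude grows by `fraction`). Perturbing a structurally masked or exactly
#' zero coefficient is rejected: 5\% of zero is zero, which carries no
#' information.
#'
#' @param model An [ssys_model()].
#' @param matrix `"g"` or `"h"`.
#' @param i,j Receiver and giver variable (index or name).
#' @param fraction Relative perturbation (default 0.05, i.e. +5\%).
#' @return The perturbed [ssys_model()].
#' @export
perturb_coefficient <- function(model, matrix = c("g", "h"), i, j,
                                fraction = 0.05) {
  stopifnot(inherits(model, "ssys_model"))
  matrix <- match.arg(matrix)
  if (is.character(i)) i <- match(i, model$variables)
  if (is.character(j)) j <- match(j, model$variables)
  mask <- if (matrix == "g") model$mask_g else model$mask_h
  val <- if (matrix == "g") model$g[i, j] else model$h[i, j]
  if (mask[i, j] || val == 0) {
    stop("cannot perturb a structurally zero coefficient ",
         matrix, "[", i, ",", j, "]")
  }
  out <- model
  if (matrix == "g") out$g[i, j] <- val * (1 + fraction)
  else out$h[i, j] <- val * (1 + fraction)
  out
}

#' Perturbation-based sensitivity ranking of network paths
#'
#' Quantifies the dominance of each interrelated coefficient in maintaining
#' the calculated time course. For each nonzero unmasked coefficient, the
#' model is re-integrated with that coefficient perturbed by `fraction`
#' (default +5\%) and the deviation from the unperturbed baseline is
#' summarized as the mean squared relative deviation over data sets,
#' variables and times:
#' \deqn{S = \frac{1}{D N T} \sum_d \sum_i \sum_t
#'   \left( \frac{PER_{d,i,t} - CAL_{d,i,t}}{CAL_{d,i,t}} \right)^2 .}
#' Scores are then scaled so the highest value on the network is 100; because
#' of this scaling any positive normalization constant (or a square root)
#' leaves the ranking and the scaled values unchanged.
#'
#' The baseline `CAL` is the model's own calculated trajectory, not observed
#' data. `D` is the number of baseline conditions (1 for a single initial
#' state; supply `x0` as a matrix with one column per condition for `D > 1`).
#'
#' @param model An [ssys_model()].
#' @param x0 Positive initial state vector, or an `n x D` matrix of initial
#'   states (one column per data set).
#' @param times Strictly increasing time vector (weeks).
#' @param fraction Relative perturbation (default 0.05).
#' @param ... Passed to [ssys_integrate()].
#' @return An object of class `"ssys_sensitivity"`: a data frame with columns
#'   `matrix`, `i`, `j` (variable names), `raw`, `scaled`, `rank`, sorted by
#'   descending scaled score (ties broken by `(matrix, i, j)` lexicographic
#'   order); the baseline time course is attached as attribute `"baseline"`.
#'   A perturbed integration that fails is recorded with `raw = Inf` and
#'   excluded from scaling, with a warning. If every raw score is zero (e.g.
#'   a baseline resting at a fixed point) scaled scores are all zero, with a
#'   warning.
#' @examples
#' m <- load_fixture_model("Ins2+/+")
#' s <- sensitivity_analysis(m, x0 = rep(1, 5), times = 3:20)
#' head(s)
#' @export
sensitivity_analysis <- function(model, x0, times, fraction = 0.05, ...) {
  stopifnot(inherits(model, "ssys_model"))
  n <- length(model$variables)
  x0 <- if (is.matrix(x0)) x0 else matrix(as.numeric(x0), ncol = 1)
  D <- ncol(x0)
  baselines <- lapply(seq_len(D), function(d) {
    ssys_integrate(model, x0[, d], times, ...)
  })
  targets <- rbind(
    coeff_positions(model$g, model$mask_g, "g"),
    coeff_positions(model$h, model$mask_h, "h"))
  if (nrow(targets) == 0) stop("model has no nonzero perturbable coefficient")
  raw <- numeric(nrow(targets))
  for (k in seq_len(nrow(targets))) {
    pm <- perturb_coefficient(model, targets$matrix[k],
                              targets$ii[k], targets$jj[k], fraction)
    dev2 <- 0
    ok <- TRUE
    for (d in seq_len(D)) {
      per <- try(ssys_integrate(pm, x0[, d], times, ...), silent = TRUE)
      if (inherits(per, "try-error")) { ok <- FALSE; break }
      rel <- (per$values - baselines[[d]]$values) / baselines[[d]]$values
      dev2 <- dev2 + mean(rel^2)
    }
    raw[k] <- if (ok) dev2 / D else Inf
  }
  finite <- is.finite(raw)
  if (any(!finite)) {
    warning(sum(!finite), " perturbed integration(s) failed; ",
            "excluded from scaling")
  }
  mx <- if (any(finite)) max(raw[finite]) else NA_real_
  scaled <- rep(NA_real_, length(raw))
  if (is.na(mx) || mx == 0) {
    if (!is.na(mx)) {
      warning("all raw sensitivities are zero (baseline at a fixed point); ",
              "scaled scores set to 0")
      scaled[finite] <- 0
    }
  } else {
    scaled[finite] <- 100 * (raw[finite] / mx)  # the max is exactly 100
  }
  out <- data.frame(matrix = targets$matrix,
                    i = model$variables[targets$ii],
                    j = model$variables[targets$jj],
                    raw = raw, scaled = scaled,
                    stringsAsFactors = FALSE)
  ord <- order(-replace(out$scaled, is.na(out$scaled), Inf),
               out$matrix, targets$ii, targets$jj)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "baseline") <- baselines
  attr(out, "fraction") <- fraction
  class(out) <- c("ssys_sensitivity", "data.frame")
  out
}

# Positions of nonzero, unmasked coefficients (row-major order).
coeff_positions <- function(mat, mask, tag) {
  keep <- !mask & mat != 0
  idx <- which(t(keep))
  n <- nrow(mat)
  ii <- ((idx - 1) %/% n) + 1
  jj <- ((idx - 1) %% n) + 1
  data.frame(matrix = rep(tag, length(idx)), ii = ii, jj = jj,
             stringsAsFactors = FALSE)
}

#' @export
print.ssys_sensitivity <- function(x, ...) {
  cat("Sensitivity ranking (", attr(x, "fraction") * 100,
      "% perturbation; top score scaled to 100)\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
plot.ssys_sensitivity <- function(x, top_k = nrow(x), ...) {
  sub <- utils::head(x, top_k)
  lab <- paste0(sub$matrix, ": ", sub$j, " → ", sub$i)
  op <- par(mar = c(4, 9, 2, 1))
  on.exit(par(op))
  barplot(rev(sub$scaled), names.arg = rev(lab), horiz = TRUE, las = 1,
          xlab = "relative sensitivity (max = 100)", ...)
  invisible(x)
}

#' Top-ranked network paths from a sensitivity report
#'
#' @param report An `"ssys_sensitivity"` report.
#' @param top_k Number of entries to return (default: all).
#' @return The first `top_k` rows (descending scaled score, ties broken by
#'   `(matrix, i, j)` order).
#' @export
rank_paths <- function(report, top_k = nrow(report)) {
  stopifnot(inherits(report, "ssys_sensitivity"), nrow(report) >= 1)
  utils::head(report, top_k)
}

#' Write a sensitivity report as CSV
#'
#' Columns: `matrix,i,j,raw,scaled,rank`.
#' @param report An `"ssys_sensitivity"` report.
#' @param path Output CSV path.
#' @export
write_sensitivity <- function(report, path) {
  write.csv(as.data.frame(report)[, c("matrix", "i", "j", "raw", "scaled", "rank")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
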