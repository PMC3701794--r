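#' Rank variables by Pearson correlation with a reference series
#'
#' Computes the Pearson correlation coefficient and two-sided p-value of each
#' candidate variable against a reference series (e.g. blood sugar), and ranks
#' variables by absolute correlation. Ranking by |r| (not signed r) matters:
#' a strongly negatively correlated variable outranks a weaker positive one.
#'
#' @param x Numeric matrix or data frame, one column per candidate variable,
#'   rows paired with `reference`.
#' @param reference Numeric reference series, same length as `nrow(x)`.
#' @param min_n Minimum number of complete pairs required per variable
#'   (default 3).
#' @return An object of class `"ssys_corr_ranking"`: a data frame with columns
#'   `variable`, `r`, `p`, sorted by `|r|` descending with ties broken by
#'   variable name. A zero-variance variable has undefined correlation and is
#'   reported with `r = NA` (ranked last), with a warning.
#' @examples
#' rank_by_correlation(data.frame(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1)),
#'                     reference = c(1, 2, 3, 4))
#' @export
rank_by_correlation <- function(x, reference, min_n = 3) {
  x <- as.data.frame(x)
  reference <- as.numeric(reference)
  stopifnot(nrow(x) == length(reference))
  res <- lapply(names(x), function(v) {
    xi <- as.numeric(x[[v]])
    ok <- is.finite(xi) & is.finite(reference)
    if (sum(ok) < min_n) {
      stop("variable '", v, "' has fewer than ", min_n, " complete pairs")
    }
    if (stats::sd(xi[ok]) == 0 || stats::sd(reference[ok]) == 0) {
      warning("variable '", v, "' has zero variance; correlation undefined")
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(xi[ok], reference[ok], method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  corr_ranking(do.call(rbind, res))
}

# Sort and class a (variable, r, p) table as a correlation ranking.
corr_ranking <- function(df) {
  ord <- order(-abs(df$r), df$variable, na.last = TRUE)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssys_corr_ranking", "data.frame")
  out
}

#' @export
print.ssys_corr_ranking <- function(x, ...) {
  cat("Correlation ranking (", nrow(x), " variables, by |r| descending)\n",
      sep = "")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Select top-ranked variables from a correlation ranking
#'
#' @param ranking An `"ssys_corr_ranking"` (from [rank_by_correlation()] or
#'   [load_fixture_correlations()]).
#' @param k Number of variables to keep (by `|r|`). If `k` exceeds the number
#'   of ranked variables, all are returned with a warning.
#' @param threshold_abs_r Alternatively, keep all variables with
#'   `|r| >= threshold_abs_r` (ignored when `k` is given).
#' @return Character vector of selected variable names.
#' @examples
#' select_top(load_fixture_correlations(), k = 5)
#' @export
select_top <- function(ranking, k = NULL, threshold_abs_r = NULL) {
  stopifnot(inherits(ranking, "ssys_corr_ranking"), nrow(ranking) >= 1)
  if (!is.null(k)) {
    if (k > nrow(ranking)) {
      warning("k = ", k, " exceeds the ", nrow(ranking),
              " ranked variables; returning all")
      k <- nrow(ranking)
    }
    return(ranking$variable[seq_len(k)])
  }
  if (is.null(threshold_abs_r)) stop("supply either 'k' or 'threshold_abs_r'")
  ranking$variable[!is.na(ranking$r) & abs(ranking$r) >= threshold_abs_r]
}
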