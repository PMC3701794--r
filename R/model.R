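#' Construct an S-system model
#'
#' An S-system describes each network component \eqn{X_i} by one synthesis and
#' one degradation power-law term,
#' \deqn{dX_i/dt = \alpha_i \prod_j X_j^{g_{ij}} - \beta_i \prod_j X_j^{h_{ij}},}
#' where the non-negative rate constants \eqn{\alpha_i} and \eqn{\beta_i} are the
#' relative inflow and outflow of \eqn{X_i}, and the real-valued exponents
#' \eqn{g_{ij}} and \eqn{h_{ij}} (the interrelated coefficients) quantify the
#' signed influence of component \eqn{j} on the synthesis and degradation of
#' component \eqn{i}. Rows index the receiving component \eqn{i}, columns the
#' giving component \eqn{j}.
#'
#' Structural zeros are carried by logical masks: `mask_g[i, j] = TRUE` marks
#' \eqn{g_{ij}} as fixed at zero (not estimated), and likewise `mask_h`. The
#' default masks leave `g` fully free and restrict `h` to its diagonal, the
#' configuration under which the number of free parameters is \eqn{n(n+3)}.
#'
#' @param alpha,beta Non-negative numeric vectors of length `n` (relative
#'   inflow and outflow rate constants).
#' @param g,h Numeric `n x n` matrices of interrelated coefficients; entry
#'   `[i, j]` is the effect of variable `j` on the synthesis (`g`) or
#'   degradation (`h`) of variable `i`.
#' @param variables Character vector of `n` variable names. Defaults to names
#'   found on `alpha` or `X1..Xn`.
#' @param mask_g,mask_h Logical `n x n` matrices; `TRUE` marks a structurally
#'   fixed zero. Defaults: `mask_g` all `FALSE` (free), `mask_h` free only on
#'   the diagonal.
#' @return An object of class `"ssys_model"`.
#' @examples
#' m <- ssys_model(alpha = 2, beta = 1, g = matrix(0), h = matrix(1))
#' steady_state(m)
#' @seealso [ssys_integrate()], [steady_state()], [count_free_parameters()],
#'   [read_ssys_model()]
#' @export
ssys_model <- function(alpha, beta, g, h, variables = NULL,
                       mask_g = NULL, mask_h = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  n <- length(alpha)
  g <- as.matrix(g)
  h <- as.matrix(h)
  if (length(beta) != n || any(dim(g) != n) || any(dim(h) != n)) {
    stop("inconsistent dimensions: alpha/beta must have length n and g/h be n x n")
  }
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(!is.finite(g)) || any(!is.finite(h))) {
    stop("model parameters must be finite")
  }
  if (any(alpha < 0) || any(beta < 0)) {
    stop("alpha and beta must be non-negative")
  }
  if (is.null(variables)) {
    variables <- names(alpha)
    if (is.null(variables)) variables <- paste0("X", seq_len(n))
  }
  if (length(variables) != n || anyDuplicated(variables)) {
    stop("'variables' must be ", n, " unique names")
  }
  if (is.null(mask_g)) mask_g <- matrix(FALSE, n, n)
  if (is.null(mask_h)) mask_h <- !diag(n) > 0  # diagonal free, off-diagonal fixed 0
  mask_g <- matrix(as.logical(mask_g), n, n)
  mask_h <- matrix(as.logical(mask_h), n, n)
  if (any(g[mask_g] != 0) || any(h[mask_h] != 0)) {
    stop("g and h must be zero at masked (structurally fixed) positions")
  }
  dimnames(g) <- dimnames(h) <- dimnames(mask_g) <- dimnames(mask_h) <-
    list(variables, variables)
  names(alpha) <- names(beta) <- variables
  structure(
    list(variables = variables, alpha = alpha, beta = beta,
         g = g, h = h, mask_g = mask_g, mask_h = mask_h),
    class = "ssys_model"
  )
}

#' Number of free (estimated) parameters of an S-system model
#'
#' Counts the unmasked entries of `alpha`, `beta`, `g` and `h`. `alpha` and
#' `beta` are always free. Under the default mask configuration (full `g`,
#' diagonal-only `h`) the count equals \eqn{n(n+3)}.
#'
#' @param model An [ssys_model()].
#' @return Integer count.
#' @examples
#' m <- load_fixture_model("Ins2+/+")
#' count_free_parameters(m)  # 5 * (5 + 3) = 40
#' @export
count_free_parameters <- function(model) {
  stopifnot(inherits(model, "ssys_model"))
  n <- length(model$variables)
  2L * n + sum(!model$mask_g) + sum(!model$mask_h)
}

#' @export
print.ssys_model <- function(x, ...) {
  n <- length(x$variables)
  cat("S-system model with", n, "variables:",
      paste(x$variables, collapse = ", "), "\n")
  cat("Free parameters:", count_free_parameters(x), "\n")
  cat("alpha:", format(x$alpha, digits = 3), "\n")
  cat("beta: ", format(x$beta, digits = 3), "\n")
  cat("g (synthesis exponents, receiver x giver):\n")
  print(x$g)
  cat("h (degradation exponents):\n")
  print(x$h)
  invisible(x)
}

#' @export
coef.ssys_model <- function(object, ...) {
  decompose <- function(mat, mask, tag) {
    idx <- which(!mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(numeric(0))
    v <- mat[!mask]
    names(v) <- paste0(tag, "[", object$variables[idx[, 1]], ",",
                       object$variables[idx[, 2]], "]")
    v
  }
  c(setNames(object$alpha, paste0("alpha[", object$variables, "]")),
    setNames(object$beta, paste0("beta[", object$variables, "]")),
    decompose(object$g, object$mask_g, "g"),
    decompose(object$h, object$mask_h, "h"))
}

#' Read or write an S-system model as JSON
#'
#' The on-disk representation is a JSON object with keys `variables`, `alpha`,
#' `beta`, `g`, `h`, `mask_g`, `mask_h`; matrices are stored row by row with
#' the receiving variable as row index and the giving variable as column index.
#'
#' @param path File path.
#' @return `read_ssys_model()` returns an [ssys_model()];
#'   `write_ssys_model()` returns `path` invisibly.
#' @export
read_ssys_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- if (is.logical(m[1])) "logical" else "double"
    m
  }
  ssys_model(alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
             g = as_mat(obj$g), h = as_mat(obj$h),
             variables = as.character(obj$variables),
             mask_g = as_mat(obj$mask_g), mask_h = as_mat(obj$mask_h))
}

#' @rdname read_ssys_model
#' @param model An [ssys_model()].
#' @export
write_ssys_model <- function(model, path) {
  stopifnot(inherits(model, "ssys_model"))
  obj <- list(variables = model$variables,
              alpha = unname(model$alpha), beta = unname(model$beta),
              g = unname(model$g), h = unname(model$h),
              mask_g = unname(model$mask_g), mask_h = unname(model$mask_h))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
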