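# Genome encoding: the free (unmasked) parameters of one S-system model as a
# flat real vector ordered (alpha, beta, g row-major, h row-major), the layout
# in which one individual of the genetic algorithm is an n x (2n + 2) block of
# real values.

# A skeleton fixes what is estimated: variable names + structural masks.
ssys_skeleton <- function(variables, mask_g = NULL, mask_h = NULL) {
  n <- length(variables)
  if (is.null(mask_g)) mask_g <- matrix(FALSE, n, n)
  if (is.null(mask_h)) mask_h <- !diag(n) > 0
  mask_g <- matrix(as.logical(mask_g), n, n)
  mask_h <- matrix(as.logical(mask_h), n, n)
  # row-major ordering of free entries (row i varies slowest)
  free_rowmajor <- function(mask) {
    idx <- which(!t(mask))  # linear indices of t(mask) = row-major walk
    if (length(idx) == 0) return(integer(0))
    # convert back to column-major linear index in the original matrix
    r <- ((idx - 1) %/% n) + 1
    co <- ((idx - 1) %% n) + 1
    (co - 1) * n + r
  }
  list(variables = variables, n = n, mask_g = mask_g, mask_h = mask_h,
       idx_g = free_rowmajor(mask_g), idx_h = free_rowmajor(mask_h))
}

skeleton_from_model <- function(model) {
  ssys_skeleton(model$variables, model$mask_g, model$mask_h)
}

n_genes <- function(skel) {
  2L * skel$n + length(skel$idx_g) + length(skel$idx_h)
}

# Per-gene box bounds: rates in bounds_rate, exponents in bounds_exponent.
genome_bounds <- function(skel, bounds_rate = c(0, 15),
                          bounds_exponent = c(-3, 3)) {
  n <- skel$n
  k <- n_genes(skel)
  lower <- c(rep(bounds_rate[1], 2 * n),
             rep(bounds_exponent[1], length(skel$idx_g) + length(skel$idx_h)))
  upper <- c(rep(bounds_rate[2], 2 * n),
             rep(bounds_exponent[2], length(skel$idx_g) + length(skel$idx_h)))
  list(lower = lower, upper = upper, k = k)
}

encode_genome <- function(model, skel = skeleton_from_model(model)) {
  c(unname(model$alpha), unname(model$beta),
    model$g[skel$idx_g], model$h[skel$idx_h])
}

decode_genome <- function(values, skel) {
  n <- skel$n
  g <- matrix(0, n, n)
  h <- matrix(0, n, n)
  ng <- length(skel$idx_g)
  g[skel$idx_g] <- values[2 * n + seq_len(ng)]
  h[skel$idx_h] <- values[2 * n + ng + seq_along(skel$idx_h)]
  ssys_model(alpha = values[1:n], beta = values[(n + 1):(2 * n)],
             g = g, h = h, variables = skel$variables,
             mask_g = skel$mask_g, mask_h = skel$mask_h)
}

# Fast path used inside the GA: genome -> parameter vector for the compiled
# right-hand side, skipping S3 construction and validation.
make_parms_packer <- function(skel, floor, ceiling) {
  n <- skel$n
  ng <- length(skel$idx_g)
  nh <- length(skel$idx_h)
  g0 <- numeric(n * n)
  h0 <- numeric(n * n)
  head <- c(n, floor, ceiling)
  tail_pad <- numeric(SSYS_PARMS_LEN - 3L - 2L * n - 2L * n * n)
  function(values) {
    g <- g0; g[skel$idx_g] <- values[2 * n + seq_len(ng)]
    h <- h0; h[skel$idx_h] <- values[2 * n + ng + seq_len(nh)]
    c(head, values[seq_len(2 * n)], g, h, tail_pad)
  }
}
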