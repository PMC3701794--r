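# Small models and datasets shared across tests.

# dX/dt = alpha - beta * X (linear decay toward alpha/beta)
linear_model <- function(alpha = 1, beta = 1) {
  ssys_model(alpha = alpha, beta = beta, g = matrix(0), h = matrix(1))
}

# pure exponential decay dX/dt = -beta * X
decay_model <- function(beta = 1) linear_model(alpha = 0, beta = beta)

# two-variable diagonal model with closed-form steady state
diag_model2 <- function() {
  ssys_model(alpha = c(1, 4), beta = c(1, 1),
             g = matrix(0, 2, 2), h = diag(c(1, 2)))
}

# a fast, well-behaved toy fitting problem
toy_decay_data <- function() {
  m <- linear_model(alpha = 2, beta = 1)
  generate_dataset(m, x0 = 3, times = seq(0, 5, by = 0.5),
                   noise = noise_spec(cv = 0))
}

tiny_control <- function(...) {
  ssys_control(population_size = 30, generations = 150, trials = 1, ...)
}
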