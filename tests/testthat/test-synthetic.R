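test_that("the packaged parameter sets carry the published values exactly", {
  wt <- load_fixture_model("Ins2+/+")
  het <- load_fixture_model("Ins2+/-")
  expect_identical(wt$variables, c("Val", "Leu", "Ile", "Ala", "Gly"))
  expect_equal(unname(wt$alpha), c(1.5, 7.5, 7.6, 7.4, 8.8))
  expect_equal(unname(wt$beta), c(1.0, 1.2, 1.1, 1.2, 1.2))
  expect_equal(wt$g["Val", "Leu"], -0.2, ignore_attr = TRUE)
  expect_equal(wt$g["Val", "Ala"], 2.0, ignore_attr = TRUE)
  expect_equal(wt$g["Gly", "Val"], 2.4, ignore_attr = TRUE)
  expect_equal(wt$h["Gly", "Gly"], 1.3, ignore_attr = TRUE)
  expect_equal(wt$h["Ala", "Ala"], 0.7, ignore_attr = TRUE)
  expect_equal(unname(het$alpha), c(4.4, 4.8, 3.8, 4.6, 2.8))
  expect_equal(unname(het$beta), c(1.5, 1.0, 1.5, 1.5, 5.6))
  expect_equal(het$g["Ala", "Val"], -0.6, ignore_attr = TRUE)
  expect_equal(het$h["Gly", "Gly"], 0.8, ignore_attr = TRUE)
  expect_equal(het$h["Val", "Val"], 0.01, ignore_attr = TRUE)
  # a Unicode minus in the condition label is accepted
  expect_equal(load_fixture_model("Ins2+/−")$alpha, het$alpha)
  expect_error(load_fixture_model("Ins2-/-"))
})

test_that("the two fixtures share a zero pattern except two self-degradation terms", {
  wt <- load_fixture_model("Ins2+/+")
  het <- load_fixture_model("Ins2+/-")
  expect_identical(wt$g == 0, het$g == 0)
  hdiff <- which((wt$h == 0) != (het$h == 0), arr.ind = TRUE)
  pos <- paste(wt$variables[hdiff[, 1]], wt$variables[hdiff[, 2]])
  expect_identical(sort(pos), c("Ala Ala", "Val Val"))
})

test_that("noise-free generation returns the clean trajectory exactly", {
  m <- load_fixture_model("Ins2+/+")
  clean <- ssys_integrate(m, rep(1, 5), 3:20, condition = "synthetic")
  gen <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(cv = 0))
  expect_identical(gen$values, clean$values)
})

test_that("noisy generation is seeded, reproducible and strictly positive", {
  m <- load_fixture_model("Ins2+/+")
  g1 <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(seed = 17))
  g2 <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(seed = 17))
  g3 <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(seed = 18))
  expect_identical(g1$values, g2$values)
  expect_false(identical(g1$values, g3$values))
  expect_true(all(g1$values > 0))
})

test_that("the noise generator reproduces the requested coefficient of variation", {
  cv <- 0.1007
  m <- linear_model(alpha = 2, beta = 1)  # X* = 2: one flat replicate point
  set.seed(77)
  draws <- replicate(1000, {
    d <- generate_dataset(m, x0 = 2, times = c(0, 1), noise = noise_spec(cv))
    d$values[1, 2, 1]
  })
  emp_cv <- stats::sd(draws) / mean(draws)
  expect_lt(abs(emp_cv - cv) / cv, 0.10)
})

test_that("generated data scores E = 0 against its generator, and ~Cv when noisy", {
  m <- load_fixture_model("Ins2+/-")
  clean <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(cv = 0))
  expect_lt(evaluate_candidate(m, clean)$total_error_percent, 1e-4)
  cv <- 0.1007
  noisy <- generate_dataset(m, rep(1, 5), 3:20, noise = noise_spec(cv, seed = 8))
  e <- evaluate_candidate(m, noisy, x0 = rep(1, 5))$total_error_percent
  expect_gt(e, 0)
  expect_lt(e, 300 * cv)
})

test_that("recovery problems are deterministic, bounded and within stated ranges", {
  p1 <- make_recovery_problem(n = 3, sparsity = 0.5, seed = 42)
  p2 <- make_recovery_problem(n = 3, sparsity = 0.5, seed = 42)
  expect_equal(coef(p1$model), coef(p2$model))
  expect_identical(p1$data$values, p2$data$values)
  v <- p1$data$values
  expect_true(all(is.finite(v)) && all(v > 0))
  expect_true(all(p1$model$alpha > 0 & p1$model$alpha <= 9))
  expect_true(all(abs(p1$model$g) <= 2.6))
  expect_true(all(diag(p1$model$g) == 0))  # no self-synthesis terms
  # the mask encodes the generator's zero pattern
  expect_identical(p1$model$mask_g, p1$model$g == 0)
})

test_that("a dense one-variable problem degenerates to relaxation kinetics", {
  p <- make_recovery_problem(n = 1, sparsity = 0, seed = 5)
  expect_identical(unname(p$model$g[1, 1]), 0)
  expect_gt(p$model$h[1, 1], 0)
  expect_identical(dim(p$data$values), c(1L, 18L, 1L))
})
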