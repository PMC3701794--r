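test_that("coefficient perturbation is multiplicative and sign-preserving", {
  m <- load_fixture_model("Ins2+/+")
  p1 <- perturb_coefficient(m, "g", "Val", "Ala", 0.05)  # 2.0 -> 2.1
  expect_equal(p1$g["Val", "Ala"], 2.1, ignore_attr = TRUE)
  p2 <- perturb_coefficient(m, "g", "Val", "Gly", 0.05)  # -1.8 -> -1.89
  expect_equal(p2$g["Val", "Gly"], -1.89, ignore_attr = TRUE)
  p3 <- perturb_coefficient(m, "h", "Gly", "Gly", 0)
  expect_equal(p3$h, m$h)
  # only the targeted coefficient changes
  diff <- p1$g != m$g
  expect_identical(sum(diff), 1L)
  expect_error(perturb_coefficient(m, "g", "Val", "Val"), "zero")
  expect_error(perturb_coefficient(m, "h", "Val", "Val"), "zero")
})

test_that("a baseline resting at a fixed point has zero raw sensitivity", {
  m <- linear_model(alpha = 1, beta = 1)  # X* = 1; 1^1.05 = 1
  expect_warning(
    s <- sensitivity_analysis(m, x0 = 1, times = 0:5),
    "fixed point")
  expect_equal(s$raw[s$matrix == "h"], 0)
  expect_equal(s$scaled[s$matrix == "h"], 0)
})

test_that("a single perturbable coefficient gets scaled score 100", {
  m <- decay_model(beta = 1)  # only h11 nonzero; start off the fixed point
  expect_error(steady_state(m))  # no steady state: baseline genuinely moves
  s <- sensitivity_analysis(m, x0 = 2, times = 0:5)
  expect_identical(nrow(s), 1L)
  expect_identical(s$scaled, 100)
  expect_gt(s$raw, 0)
})

test_that("the report covers each nonzero unmasked coefficient exactly once", {
  m <- load_fixture_model("Ins2+/+")
  s <- sensitivity_analysis(m, rep(1, 5), 3:20)
  expect_identical(nrow(s), sum(m$g != 0) + sum(m$h != 0))  # 16 + 2
  expect_identical(anyDuplicated(paste(s$matrix, s$i, s$j)), 0L)
  expect_equal(max(s$scaled), 100)
  expect_true(all(s$raw >= 0))
  expect_true(all(diff(s$scaled) <= 1e-12))  # sorted descending
  expect_identical(s$rank, seq_len(nrow(s)))
})

test_that("shrinking the perturbation shrinks every raw score", {
  m <- diag_model2()
  m$g[1, 2] <- 0.8  # add one cross influence so the model is interactive
  s5 <- sensitivity_analysis(m, x0 = c(2, 1), times = 0:6, fraction = 0.05)
  s1 <- sensitivity_analysis(m, x0 = c(2, 1), times = 0:6, fraction = 0.01)
  key <- paste(s5$matrix, s5$i, s5$j)
  m1 <- s1$raw[match(key, paste(s1$matrix, s1$i, s1$j))]
  expect_true(all(m1 < s5$raw))
})

test_that("rank_paths preserves order, breaks ties lexicographically, honors top_k", {
  m <- load_fixture_model("Ins2+/+")
  s <- sensitivity_analysis(m, rep(1, 5), 3:20)
  r <- rank_paths(s)
  expect_identical(r$scaled, sort(s$scaled, decreasing = TRUE))
  top <- rank_paths(s, top_k = 1)
  expect_identical(nrow(top), 1L)
  expect_identical(top$scaled, 100)
  # a perfectly symmetric model produces tied scores reported in (matrix, i, j) order
  sym <- ssys_model(alpha = c(2, 2), beta = c(1, 1),
                    g = matrix(c(0, 0.5, 0.5, 0), 2, 2),
                    h = diag(c(1, 1)))
  ss <- sensitivity_analysis(sym, x0 = c(1.5, 1.5), times = 0:6)
  tied <- ss[ss$matrix == "g", ]
  expect_equal(tied$scaled[1], tied$scaled[2], tolerance = 1e-6)
  expect_identical(tied$i, c("X1", "X2"))  # lexicographic tie-break
})

test_that("sensitivity CSV export has the documented columns", {
  m <- diag_model2()
  s <- sensitivity_analysis(m, x0 = c(2, 1), times = 0:6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity(s, path)
  df <- read.csv(path)
  expect_identical(names(df), c("matrix", "i", "j", "raw", "scaled", "rank"))
  expect_identical(nrow(df), nrow(s))
})
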