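test_that("a model compared with itself has no sign reversals", {
  m <- load_fixture_model("Ins2+/+")
  cmp <- compare_networks(m, m)
  expect_identical(sum(cmp$status == "sign-reversal"), 0L)
  expect_true(all(cmp$status %in% c("same-sign", "absent")))
  # every estimable position appears exactly once: 25 g + 5 h diagonal
  expect_identical(nrow(cmp), 30L)
  expect_identical(anyDuplicated(paste(cmp$matrix, cmp$i, cmp$j)), 0L)
})

test_that("opposite-sign coefficients are flagged as reversals", {
  a <- ssys_model(alpha = c(1, 1), beta = c(1, 1),
                  g = matrix(c(0, 1, 0, 0), 2, 2), h = diag(c(1, 1)))
  b <- ssys_model(alpha = c(1, 1), beta = c(1, 1),
                  g = matrix(c(0, -1, 0, 0), 2, 2), h = diag(c(1, 1)))
  cmp <- compare_networks(a, b)
  rev <- cmp[cmp$status == "sign-reversal", ]
  expect_identical(nrow(rev), 1L)
  expect_identical(rev$i, "X2")
  expect_identical(rev$j, "X1")
})

test_that("the two packaged condition networks differ at the printed positions", {
  wt <- load_fixture_model("Ins2+/+")
  het <- load_fixture_model("Ins2+/-")
  cmp <- compare_networks(wt, het)
  rev <- cmp[cmp$status == "sign-reversal", ]
  # the printed tables have opposite signs at exactly these four g positions
  got <- sort(paste(rev$matrix, rev$i, rev$j))
  expect_identical(got, sort(c("g Val Gly",   # glycine to valine
                               "g Ala Val",   # valine to alanine
                               "g Ala Leu",   # leucine to alanine
                               "g Ile Ala"))) # alanine to isoleucine
  # h differs structurally: Ala self-degradation only in the control network,
  # Val self-degradation only in the hyperglycemic one
  expect_identical(cmp$status[cmp$matrix == "h" & cmp$i == "Ala" & cmp$j == "Ala"],
                   "only-A")
  expect_identical(cmp$status[cmp$matrix == "h" & cmp$i == "Val" & cmp$j == "Val"],
                   "only-B")
})

test_that("comparison flags the same reversal positions in either direction", {
  wt <- load_fixture_model("Ins2+/+")
  het <- load_fixture_model("Ins2+/-")
  ab <- compare_networks(wt, het)
  ba <- compare_networks(het, wt)
  key <- function(cmp) sort(paste(cmp$matrix, cmp$i, cmp$j)[cmp$status == "sign-reversal"])
  expect_identical(key(ab), key(ba))
})

test_that("SIF export follows the giver-to-receiver sign convention", {
  m <- ssys_model(alpha = c(1, 1), beta = c(1, 1),
                  g = matrix(c(0, 0, 1.4, 0), 2, 2), h = diag(c(0, 0)),
                  variables = c("X1", "X2"))
  path <- withr::local_tempfile(fileext = ".sif")
  export_network(m, path)
  expect_identical(readLines(path), "X2\tactivates\tX1")
})

test_that("GraphML round-trips nodes, edge count and signs", {
  m <- load_fixture_model("Ins2+/+")
  s <- sensitivity_analysis(m, rep(1, 5), 3:20)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(m, path, report = s)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), sum(m$g != 0) + sum(m$h != 0))
  signs <- igraph::edge_attr(g, "sign")
  expect_equal(sum(signs == "activation"),
               sum(m$g > 0) + sum(m$h > 0))
  expect_true(all(is.finite(igraph::edge_attr(g, "sensitivity"))))
})

test_that("an empty network exports nodes only", {
  m <- ssys_model(alpha = c(1, 1), beta = c(1, 1),
                  g = matrix(0, 2, 2), h = diag(c(0, 0)))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(m, sif)
  expect_identical(readLines(sif), c("X1", "X2"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(m, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 0)
})
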