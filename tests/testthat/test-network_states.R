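test_that("per-participant normalization maps ranges to [0, 1]", {
  v <- rbind(rep(0.2, 4), rep(0.8, 4))
  out <- normalize_centralities(v, c("p1", "p1"))
  expect_equal(out, rbind(rep(0, 4), rep(1, 4)))

  same <- rbind(rep(0.5, 4), rep(0.5, 4))
  expect_warning(res <- normalize_centralities(same, c("p1", "p1")),
                 "constant")
  expect_true(all(res == 0))

  # normalization is per participant: rescaling one participant's raw
  # vectors leaves every participant's normalized output unchanged
  set.seed(1)
  v2 <- matrix(runif(40), 10, 4)
  ids <- rep(c("p1", "p2"), each = 5)
  base <- normalize_centralities(v2, ids)
  v3 <- v2
  v3[ids == "p2", ] <- v3[ids == "p2", ] * 10
  expect_equal(normalize_centralities(v3, ids), base, tolerance = 1e-12)

  expect_error(normalize_centralities(v2[1, , drop = FALSE], "p1"),
               "fewer than 2")
})

test_that("similarity edges are clamped Spearman correlations", {
  set.seed(2)
  vecs <- matrix(runif(12 * 8), 12, 8)
  vecs[2, ] <- vecs[1, ]                   # identical pair
  vecs[4, ] <- max(vecs[3, ]) + min(vecs[3, ]) - vecs[3, ]  # reversed ranks
  g <- build_similarity_graph(vecs)
  raw <- attr(g, "raw_similarity")
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(w[1, 2], 1)
  expect_equal(raw[3, 4], -1, tolerance = 1e-12)
  expect_equal(w[3, 4], 0)
  for (pair in list(c(1, 5), c(6, 7), c(9, 12))) {
    expect_equal(raw[pair[1], pair[2]],
                 oracle_spearman(vecs[pair[1], ], vecs[pair[2], ]),
                 tolerance = 1e-12)
  }

  vecs[6, ] <- 0.5                          # constant vector
  expect_warning(g2 <- build_similarity_graph(vecs), "constant")
  w2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_true(all(w2[6, ] == 0))

  expect_error(build_similarity_graph(vecs[1:5, ]), "at least 10")
})

test_that("planted vector groups are recovered as states", {
  skip_if_not_installed("mclust")
  # two well-separated groups: perfect recovery
  for (s in 1:10) {
    set.seed(s)
    prof <- rbind(c(1:8), c(8:1)) / 8
    truth <- rep(1:2, each = 10)
    vecs <- prof[truth, ] + matrix(rnorm(160, sd = 0.02), 20, 8)
    g <- build_similarity_graph(vecs)
    catal <- detect_states(g, seed = s, vectors = vecs)
    expect_equal(mclust::adjustedRandIndex(as.integer(catal$assignment),
                                           truth), 1)
  }
})

test_that("state detection is deterministic and input-order invariant", {
  skip_if_not_installed("mclust")
  set.seed(3)
  prof <- planted_profiles(3)
  truth <- rep(1:4, each = 15)
  vecs <- prof[truth, ] + matrix(rnorm(60 * 8, sd = 0.1), 60, 8)
  g <- build_similarity_graph(vecs)
  a <- detect_states(g, seed = 11, vectors = vecs)
  b <- detect_states(g, seed = 11, vectors = vecs)
  expect_identical(a$assignment, b$assignment)

  perm <- sample(60)
  gp <- build_similarity_graph(vecs[perm, ])
  cp <- detect_states(gp, seed = 11, vectors = vecs[perm, ])
  expect_gte(mclust::adjustedRandIndex(as.integer(a$assignment)[perm],
                                       as.integer(cp$assignment)), 0.99)
})

test_that("centroids, coverage, and labels follow the assignment", {
  vecs <- rbind(c(0, 1), c(1, 0), c(0.5, 0.5), c(0.4, 0.6))
  catal <- structure(
    list(state_labels = c("A", "B"),
         assignment = factor(c("A", "A", "B", "B"), levels = c("A", "B")),
         centroids = NULL, coverage_ratio = c(A = 0.5, B = 0.5)),
    class = "state_catalog")
  out <- state_centroids(catal, vecs, durations = c(2, 2, 1, 1))
  expect_equal(unname(out$centroids["A", ]), c(0.5, 0.5))
  expect_equal(unname(out$coverage_ratio), c(4 / 6, 2 / 6))
  expect_equal(sum(out$coverage_ratio), 1)

  # coverage ordering defines the A, B, C labels
  set.seed(4)
  prof <- planted_profiles(4)
  truth <- c(rep(1, 40), rep(2, 12), rep(3, 12), rep(4, 12))
  vecs2 <- prof[truth, ] + matrix(rnorm(76 * 8, sd = 0.05), 76, 8)
  catal2 <- detect_states(build_similarity_graph(vecs2), seed = 5,
                          vectors = vecs2)
  expect_equal(catal2$coverage_ratio,
               sort(catal2$coverage_ratio, decreasing = TRUE))
  expect_equal(names(which.max(table(catal2$assignment))), "A")
})

test_that("cross-band centroid correlations form a valid matrix", {
  set.seed(6)
  cents <- list(
    alpha = matrix(runif(32), 4, 8, dimnames = list(LETTERS[1:4], NULL)),
    theta = matrix(runif(32), 4, 8, dimnames = list(LETTERS[1:4], NULL))
  )
  m <- cross_band_state_correlation(cents)
  expect_equal(dim(m), c(8, 8))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 8))
  expect_equal(m["alpha.A", "theta.C"],
               oracle_pearson(cents$alpha["A", ], cents$theta["C", ]),
               tolerance = 1e-12)
})
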