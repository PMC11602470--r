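complete_layer <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

path3_layer <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w
}

test_that("closeness matches hand-derived values on canonical graphs", {
  net <- new_multiplex(list(A = complete_layer(4), B = complete_layer(4)),
                       normalized = TRUE)
  expect_equal(unname(layer_closeness(net, 1)), rep(1, 4))
  expect_equal(unname(overlapping_closeness(net)), rep(1, 4))

  # 3-node path: end nodes have mean distance (1 + 2) / 2
  pnet <- new_multiplex(list(A = path3_layer(), B = path3_layer()),
                        normalized = TRUE)
  expect_equal(unname(layer_closeness(pnet, 1)), c(2 / 3, 1, 2 / 3))

  # layer 1 complete, layer 2 path: overlapping is the layer mean
  mixed <- new_multiplex(list(A = complete_layer(3), B = path3_layer()),
                         normalized = TRUE)
  expect_equal(unname(overlapping_closeness(mixed)), c(5 / 6, 1, 5 / 6))

  # isolated node makes everyone unreachable from somewhere
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  inet <- new_multiplex(list(A = iso, B = iso), normalized = TRUE)
  expect_equal(unname(layer_closeness(inet, 1)), c(0, 0, 0))
})

test_that("closeness agrees with the exhaustive-path oracle on small graphs", {
  grid_vals <- c(0, 0.25, 0.5, 1)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:5, 1)
    w <- matrix(sample(grid_vals, n * n, replace = TRUE), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    net <- new_multiplex(list(L = w), normalized = TRUE)
    expect_equal(unname(layer_closeness(net, 1)), oracle_closeness(w),
                 tolerance = 1e-12)
  }
})

test_that("closeness agrees with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    set.seed(s + 50)
    n <- 8
    w <- matrix(runif(n * n, 0.05, 1), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    net <- new_multiplex(list(L = w), normalized = TRUE)
    g <- igraph::graph_from_adjacency_matrix(1 / w * (w > 0),
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g, weights = igraph::E(g)$weight)
    ours <- layer_closeness(net, 1)
    theirs <- sapply(seq_len(n), function(i) 1 / mean(d[i, -i]))
    expect_equal(unname(ours), theirs, tolerance = 1e-10)
  }
})

test_that("raising an edge weight never lowers any closeness", {
  set.seed(11)
  w <- matrix(runif(25, 0, 1), 5, 5)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  base <- oracle_closeness(w)
  for (rep in 1:10) {
    i <- sample(5, 1)
    j <- sample(setdiff(1:5, i), 1)
    w2 <- w
    w2[i, j] <- w2[j, i] <- min(1, w[i, j] + runif(1, 0, 0.5))
    net <- new_multiplex(list(L = w2), normalized = TRUE)
    expect_true(all(layer_closeness(net, 1) >= base - 1e-12))
  }
})

test_that("centrality matrices are consistent, equivariant, layer-order invariant", {
  net <- random_multiplex(8, seed = 12)
  cm <- centrality_matrix(net)
  expect_equal(dim(cm$values), c(8, 2))
  expect_equal(cm$overlapping, rowMeans(cm$values))

  perm <- sample(8)
  pnet <- new_multiplex(lapply(net$layers, function(l) l[perm, perm]),
                        normalized = TRUE)
  pcm <- centrality_matrix(pnet)
  expect_equal(unname(pcm$overlapping), unname(cm$overlapping[perm]),
               tolerance = 1e-12)

  swapped <- new_multiplex(net$layers[c(2, 1)], normalized = TRUE)
  expect_equal(unname(overlapping_closeness(swapped)),
               unname(cm$overlapping), tolerance = 1e-12)
})

test_that("the coupled interlayer convention never lowers closeness", {
  for (s in 1:5) {
    net <- random_multiplex(6, seed = s + 70)
    within <- centrality_matrix(net, interlayer = "within")
    coupled <- centrality_matrix(net, interlayer = "coupled")
    per_layer_max <- pmax(within$values[, 1], within$values[, 2])
    expect_true(all(coupled$overlapping >= per_layer_max - 1e-12))
  }
})

test_that("interlayer heterogeneity reflects layer agreement", {
  w <- matrix(runif(64), 8, 8)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w <- normalize_layer(w)
  same <- new_multiplex(list(A = w, B = w), normalized = TRUE)
  expect_equal(interlayer_heterogeneity(same), 1)

  flipped <- 1 - w
  diag(flipped) <- 0
  anti <- new_multiplex(list(A = w, B = flipped), normalized = FALSE)
  expect_equal(interlayer_heterogeneity(anti), -1)

  # independent layers rarely correlate strongly over 28 edges
  below <- sum(sapply(1:100, function(s) {
    abs(interlayer_heterogeneity(random_multiplex(8, seed = s + 200))) < 0.5
  }))
  expect_gte(below, 93)

  flat <- matrix(1, 4, 4)
  diag(flat) <- 0
  degen <- new_multiplex(list(A = flat, B = flat), normalized = TRUE)
  expect_warning(h <- interlayer_heterogeneity(degen), "variance")
  expect_true(is.na(h))
})
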