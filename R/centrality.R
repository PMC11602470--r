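#' Within-layer node closeness centrality
#'
#' Edge distance is the inverse of the (normalized) connection strength;
#' zero-weight edges are absent (infinite distance). The closeness of node i
#' is the inverse of its mean shortest-path distance to the other `n - 1`
#' nodes; a node that cannot reach every other node has closeness 0 (the
#' limit of an infinite mean distance).
#'
#' Shortest paths are computed by Floyd-Warshall, which at the 8-node scale
#' of an EEG montage costs a handful of vectorized matrix operations and is
#' called thousands of times per recording by the segmenter.
#'
#' @param net a normalized `multiplex_network`.
#' @param layer layer index or name.
#' @return Numeric vector of length `n_nodes`.
#' @export
layer_closeness <- function(net, layer) {
  stopifnot(inherits(net, "multiplex_network"))
  if (!net$normalized) stop("network must be normalized")
  w <- net$layers[[layer]]
  if (is.null(w)) stop("invalid layer")
  closeness_from_weights(w)
}

closeness_from_weights <- function(w) {
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes")
  d <- shortest_distances(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    cc[i] <- if (any(!is.finite(di))) 0 else 1 / mean(di)
  }
  names(cc) <- rownames(w)
  cc
}

# All-pairs shortest path distances with edge distance = 1 / weight
# (0-weight edges absent). Floyd-Warshall on the dense matrix.
shortest_distances <- function(w) {
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    via_k <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, via_k)
  }
  d
}

#' Overlapping node closeness centrality
#'
#' The per-node average across layers of the within-layer closeness: for m
#' layers, `CC_i = (1/m) * sum_l c_i^[l]`. With the default
#' `interlayer = "within"` convention each layer's shortest paths stay inside
#' that layer. The alternative `interlayer = "coupled"` honors zero-cost
#' inter-layer hops at node replicas: a path may switch layer at any node for
#' free, which for two layers is equivalent to shortest paths on the
#' elementwise-maximum-weight graph, and every layer then shares that common
#' closeness.
#'
#' @param net a normalized `multiplex_network`.
#' @param interlayer `"within"` (default) or `"coupled"`.
#' @return Numeric vector of length `n_nodes`.
#' @export
overlapping_closeness <- function(net, interlayer = c("within", "coupled")) {
  interlayer <- match.arg(interlayer)
  cm <- centrality_matrix(net, interlayer = interlayer)
  cm$overlapping
}

#' Per-layer and overlapping centralities of a multiplex network
#'
#' @inheritParams overlapping_closeness
#' @return A `centrality_matrix` object: `values` is the n_nodes x n_layers
#'   matrix of within-layer closenesses, `overlapping` its row means.
#' @export
centrality_matrix <- function(net, interlayer = c("within", "coupled")) {
  stopifnot(inherits(net, "multiplex_network"))
  interlayer <- match.arg(interlayer)
  if (!net$normalized) stop("network must be normalized")
  if (identical(interlayer, "coupled")) {
    wmax <- Reduce(pmax, net$layers)
    cc <- closeness_from_weights(wmax)
    values <- matrix(cc, nrow = net$n_nodes, ncol = length(net$layers))
  } else {
    values <- vapply(net$layers, closeness_from_weights,
                     numeric(net$n_nodes))
    values <- matrix(values, nrow = net$n_nodes)
  }
  colnames(values) <- net$layer_labels
  labels <- rownames(net$layers[[1]])
  if (is.null(labels)) labels <- paste0("node", seq_len(net$n_nodes))
  rownames(values) <- labels
  structure(
    list(values = values,
         overlapping = rowMeans(values),
         node_labels = labels),
    class = "centrality_matrix"
  )
}

#' @export
print.centrality_matrix <- function(x, ...) {
  cat(sprintf("<centrality_matrix> %d nodes x %d layers\n",
              nrow(x$values), ncol(x$values)))
  print(cbind(x$values, overlapping = x$overlapping))
  invisible(x)
}

#' Inter-layer heterogeneity of a two-layer multiplex network
#'
#' Pearson correlation between the vectorized upper-triangle edge weights of
#' the two layers. Values near 1 mean the layers carry redundant structure;
#' values near 0, complementary structure.
#'
#' @param net a `multiplex_network` with exactly 2 layers and >= 3 node
#'   pairs.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   layer's edges have zero variance.
#' @export
interlayer_heterogeneity <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  if (length(net$layers) != 2L) stop("heterogeneity is defined for 2 layers")
  ut <- upper.tri(net$layers[[1]])
  e1 <- net$layers[[1]][ut]
  e2 <- net$layers[[2]][ut]
  if (length(e1) < 3L) stop("need at least 3 distinct edge positions")
  if (stats::sd(e1) == 0 || stats::sd(e2) == 0) {
    warning("zero edge-weight variance: heterogeneity undefined")
    return(NA_real_)
  }
  stats::cor(e1, e2)
}
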