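#' Per-segment overlapping centrality vectors
#'
#' Computes the overlapping node closeness centrality vector of every
#' segment of a segmented recording; these vectors are the features from
#' which recurring network states are defined.
#'
#' @param rec a `banded_recording`.
#' @param seg a `segmentation` of that recording.
#' @param interlayer centrality convention, see [overlapping_closeness()].
#' @return List with `vectors` (segments x nodes matrix) and `meta` (data
#'   frame: participant, trial, band, segment, start, end, duration).
#' @export
segment_centralities <- function(rec, seg, interlayer = "within") {
  stopifnot(inherits(rec, "banded_recording"), inherits(seg, "segmentation"))
  rate <- rec$sampling_rate
  spans <- seg$spans
  vecs <- matrix(NA_real_, nrow = nrow(spans), ncol = nrow(rec$data))
  colnames(vecs) <- rec$channel_names
  for (k in seq_len(nrow(spans))) {
    i <- (round(spans$start[k] * rate) + 1L):(round(spans$end[k] * rate))
    cm <- segment_overlapping(rec$data[, i, drop = FALSE], c(NA, NA), rate,
                              interlayer)
    vecs[k, ] <- cm$overlapping
  }
  meta <- data.frame(
    participant = rec$participant_id,
    trial = rec$trial_label,
    band = rec$band,
    segment = seq_len(nrow(spans)),
    start = spans$start,
    end = spans$end,
    duration = spans$end - spans$start,
    stringsAsFactors = FALSE
  )
  list(vectors = vecs, meta = meta)
}

#' Per-participant min-max normalization of centrality vectors
#'
#' To mitigate individual differences in overall centrality scale, each
#' component of each participant's vectors is mapped to
#' `(c - min) / (max - min)`, with the minimum and maximum taken over all of
#' that participant's segments and trials (within the band being analyzed).
#' A component with zero range across a participant is set to 0 with a
#' warning.
#'
#' @param vectors numeric matrix, segments x nodes, pooled over participants.
#' @param participants vector with one participant id per row of `vectors`.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_centralities <- function(vectors, participants) {
  vectors <- as.matrix(vectors)
  if (length(participants) != nrow(vectors)) {
    stop("one participant id per vector is required")
  }
  out <- vectors
  for (p in unique(participants)) {
    rows <- which(participants == p)
    if (length(rows) < 2L) {
      stop(sprintf("participant %s contributes fewer than 2 vectors", p))
    }
    block <- vectors[rows, , drop = FALSE]
    lo <- apply(block, 2, min)
    hi <- apply(block, 2, max)
    rng <- hi - lo
    zero <- rng == 0
    if (any(zero)) {
      warning(sprintf("participant %s: %d constant component(s) set to 0",
                      p, sum(zero)))
      rng[zero] <- 1
    }
    normed <- sweep(sweep(block, 2, lo), 2, rng, "/")
    normed[, zero] <- 0
    out[rows, ] <- normed
  }
  out
}

#' Segment-similarity graph
#'
#' Builds the complete weighted graph whose nodes are segments and whose
#' edge weights are Spearman rank correlations between the segments'
#' normalized overlapping-centrality vectors. Negative correlations are
#' clamped to 0, since modularity-based community detection assumes
#' nonnegative weights. Constant vectors (undefined ranks) get all-zero
#' edges with a warning.
#'
#' @param vectors numeric matrix, segments x nodes (>= 10 segments, >= 3
#'   nodes).
#' @return An `igraph` weighted undirected graph; the pre-clamping
#'   correlation matrix is attached as attribute `"raw_similarity"`.
#' @export
build_similarity_graph <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 10L) stop("need at least 10 segment vectors")
  if (ncol(vectors) < 3L) stop("vectors must have at least 3 components")
  constant <- apply(vectors, 1, function(v) stats::sd(v) == 0)
  s <- suppressWarnings(stats::cor(t(vectors), method = "spearman"))
  if (any(constant)) {
    warning(sprintf("%d constant vector(s): their edges set to 0",
                    sum(constant)))
    s[constant, ] <- 0
    s[, constant] <- 0
  }
  s[!is.finite(s)] <- 0
  w <- pmax(s, 0)
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  attr(g, "raw_similarity") <- s
  g
}

#' Detect recurring network states by Louvain community detection
#'
#' Runs modularity maximization on the segment-similarity graph. Communities
#' are the recurring multilayer network states; they are ordered by
#' descending coverage (total assigned segment time, or segment count when
#' durations are not supplied) and labeled A, B, C, ... Communities holding
#' less than `min_coverage` of total time are merged into the community with
#' the most-correlated centroid, which keeps downstream observation
#' alphabets free of near-empty symbols.
#'
#' @param graph segment-similarity graph from [build_similarity_graph()].
#' @param seed integer seed (community detection is randomized).
#' @param resolution Louvain resolution parameter (default 1).
#' @param vectors the normalized vectors behind the graph (needed for
#'   centroid-based merging; optional).
#' @param durations per-segment durations in seconds (optional; counts used
#'   otherwise).
#' @param min_coverage merge threshold as a fraction of total time (default
#'   0.01).
#' @return A `state_catalog`: `state_labels`, `assignment` (factor over
#'   segments), `centroids` (states x nodes, when `vectors` given),
#'   `coverage_ratio`.
#' @export
detect_states <- function(graph, seed = 1, resolution = 1,
                          vectors = NULL, durations = NULL,
                          min_coverage = 0.01) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("need at least 2 segments")
  w <- igraph::E(graph)$weight
  if (is.null(w) || sum(w) <= 0) {
    warning("all-zero similarity: single community")
    membership <- rep(1L, n)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    membership <- igraph::membership(
      igraph::cluster_louvain(graph, resolution = resolution))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  }
  membership <- as.integer(membership)
  if (is.null(durations)) durations <- rep(1, n)
  total <- sum(durations)

  # merge tiny communities into their most-correlated neighbor
  if (!is.null(vectors)) {
    repeat {
      ids <- sort(unique(membership))
      cov <- vapply(ids, function(k) sum(durations[membership == k]) / total,
                    numeric(1))
      small <- ids[cov < min_coverage]
      if (length(small) == 0L || length(ids) <= 1L) break
      k <- small[which.min(cov[match(small, ids)])]
      cen <- function(id) colMeans(vectors[membership == id, , drop = FALSE])
      others <- setdiff(ids, k)
      sim <- vapply(others, function(o) stats::cor(cen(k), cen(o)), numeric(1))
      sim[!is.finite(sim)] <- -Inf
      membership[membership == k] <- others[which.max(sim)]
    }
  }

  ids <- sort(unique(membership))
  cov <- vapply(ids, function(k) sum(durations[membership == k]) / total,
                numeric(1))
  ord <- order(cov, decreasing = TRUE)
  labels <- state_label_seq(length(ids))
  relabel <- stats::setNames(labels, ids[ord])
  assignment <- factor(relabel[as.character(membership)], levels = labels)
  centroids <- NULL
  if (!is.null(vectors)) {
    centroids <- t(vapply(labels, function(lab) {
      colMeans(vectors[assignment == lab, , drop = FALSE])
    }, numeric(ncol(vectors))))
    rownames(centroids) <- labels
  }
  structure(
    list(state_labels = labels,
         assignment = assignment,
         centroids = centroids,
         coverage_ratio = stats::setNames(sort(cov, decreasing = TRUE), labels)),
    class = "state_catalog"
  )
}

state_label_seq <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else
    paste0("S", sprintf("%02d", seq_len(n)))
}

#' @export
print.state_catalog <- function(x, ...) {
  cat(sprintf("<state_catalog> %d states over %d segments\n",
              length(x$state_labels), length(x$assignment)))
  print(round(x$coverage_ratio, 3))
  invisible(x)
}

#' Recompute state centroids and coverage ratios
#'
#' @param catalog a `state_catalog`.
#' @param vectors the normalized vectors the catalog assigns (segments x
#'   nodes).
#' @param durations per-segment durations in seconds (optional).
#' @return List with `centroids` (states x nodes) and `coverage_ratio`;
#'   empty states are excluded with a warning.
#' @export
state_centroids <- function(catalog, vectors, durations = NULL) {
  stopifnot(inherits(catalog, "state_catalog"))
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(catalog$assignment)) {
    stop("catalog assignment does not cover the vectors")
  }
  if (is.null(durations)) durations <- rep(1, nrow(vectors))
  counts <- table(catalog$assignment)
  keep <- names(counts)[counts > 0]
  if (length(keep) < length(catalog$state_labels)) {
    warning("empty state(s) excluded")
  }
  centroids <- t(vapply(keep, function(lab) {
    colMeans(vectors[catalog$assignment == lab, , drop = FALSE])
  }, numeric(ncol(vectors))))
  rownames(centroids) <- keep
  cov <- vapply(keep, function(lab) {
    sum(durations[catalog$assignment == lab])
  }, numeric(1)) / sum(durations)
  list(centroids = centroids, coverage_ratio = cov)
}

#' Pearson correlations among state centroids across bands
#'
#' Given per-band centroid matrices (states x nodes), returns the Pearson
#' correlation matrix over all state-band pairs; rows and columns are named
#' `band.state`. Constant centroids give `NA` rows/columns.
#'
#' @param centroids named list (by band) of centroid matrices sharing the
#'   node dimension.
#' @return Symmetric correlation matrix.
#' @export
cross_band_state_correlation <- function(centroids) {
  if (is.null(names(centroids))) {
    names(centroids) <- paste0("band", seq_along(centroids))
  }
  nodes <- unique(vapply(centroids, ncol, integer(1)))
  if (length(nodes) != 1L) stop("centroid matrices must share node dimension")
  all_rows <- do.call(rbind, centroids)
  rownames(all_rows) <- unlist(lapply(names(centroids), function(b) {
    paste(b, rownames(centroids[[b]]), sep = ".")
  }))
  suppressWarnings(stats::cor(t(all_rows)))
}
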