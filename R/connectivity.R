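#' Analytic signal via the Hilbert transform
#'
#' Computes the analytic signal of each channel by the standard FFT
#' construction (doubling positive frequencies, zeroing negative ones). The
#' amplitude envelope is `Mod()` of the result and the instantaneous phase is
#' `Arg()`.
#'
#' @param segment numeric matrix, channels x samples.
#' @return Complex matrix of the same shape.
#' @export
analytic_signal <- function(segment) {
  segment <- as.matrix(segment)
  n <- ncol(segment)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  spec <- stats::mvfft(t(segment)) * h
  t(stats::mvfft(spec, inverse = TRUE)) / n
}

check_segment <- function(segment) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 2L) stop("need at least 2 channels")
  if (ncol(segment) < 8L) stop("need at least 8 samples")
  if (any(!is.finite(segment))) stop("segment contains non-finite values")
  segment
}

#' Amplitude envelope correlation
#'
#' Entry (i, j) is the absolute Pearson correlation between the Hilbert
#' amplitude envelopes of channels i and j; the absolute value is taken
#' because negative envelope correlations carry no meaning for the network
#' weights used here. Pairs involving a constant-envelope channel (undefined
#' correlation) are set to 0 with a warning.
#'
#' @param segment numeric matrix, channels x samples.
#' @return Symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
aec <- function(segment) {
  segment <- check_segment(segment)
  env <- Mod(analytic_signal(segment))
  sds <- apply(env, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("constant-envelope channel(s): correlations set to 0")
  }
  m <- suppressWarnings(abs(stats::cor(t(env))))
  if (any(degenerate)) {
    m[degenerate, ] <- 0
    m[, degenerate] <- 0
  }
  m[!is.finite(m)] <- 0
  diag(m) <- 0
  rownames(m) <- colnames(m) <- rownames(segment)
  m
}

#' Imaginary phase-locking value
#'
#' For channels i and j with Hilbert analytic phases `phi_i(n)`, `phi_j(n)`
#' over the `N` samples of the segment, the IPLV is
#' `|Im( sum_n exp(1i * (phi_i(n) - phi_j(n))) )| / N`. Zero-lag coupling
#' (identical phases, as produced by volume conduction) yields exactly 0,
#' which is the reason this estimator is used for the second network layer.
#'
#' @param segment numeric matrix, channels x samples.
#' @return Symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
iplv <- function(segment) {
  segment <- check_segment(segment)
  a <- analytic_signal(segment)
  mod_a <- Mod(a)
  degenerate <- apply(mod_a == 0, 1, any)
  if (any(degenerate)) {
    warning("channel(s) with undefined phase: pairs set to 0")
  }
  z <- a / ifelse(mod_a == 0, 1, mod_a)     # unit phasors exp(1i * phi)
  # sum_n exp(1i (phi_i - phi_j)) = row-wise complex inner product z_i z_j*
  s <- z %*% Conj(t(z))
  m <- abs(Im(s)) / ncol(segment)
  if (any(degenerate)) {
    m[degenerate, ] <- 0
    m[, degenerate] <- 0
  }
  diag(m) <- 0
  rownames(m) <- colnames(m) <- rownames(segment)
  m
}

#' Min-max normalization of a connectivity layer
#'
#' Maps each off-diagonal edge weight e to `(e - r_min) / (r_max - r_min)`,
#' where `r_min` and `r_max` are the minimum and maximum off-diagonal weights
#' of the layer. When all edges are equal the layer is mapped to all-ones
#' (rather than zeros) so that it remains connected for shortest-path
#' centrality; a zero weight would mean an infinite distance downstream.
#'
#' @param weights symmetric numeric matrix.
#' @return Symmetric matrix with off-diagonal entries in `[0, 1]`.
#' @export
normalize_layer <- function(weights) {
  weights <- as.matrix(weights)
  off <- weights[upper.tri(weights) | lower.tri(weights)]
  if (any(!is.finite(off))) stop("non-finite edge weights")
  r_min <- min(off)
  r_max <- max(off)
  out <- weights
  if (r_max == r_min) {
    warning("degenerate layer (all edges equal): normalized to 1")
    out[] <- 1
  } else {
    out[] <- (weights - r_min) / (r_max - r_min)
  }
  diag(out) <- 0
  out
}

#' Construct a two-layer weighted multiplex network from a data segment
#'
#' Layer 1 carries min-max-normalized amplitude envelope correlations, layer 2
#' min-max-normalized imaginary phase-locking values. Nodes are channels;
#' inter-layer edges link a node only to its own replica and carry no
#' traversal cost.
#'
#' @param segment numeric matrix, channels x samples.
#' @param span optional `(start, end)` in seconds, recorded on the result.
#' @return A `multiplex_network` object with fields `n_nodes`,
#'   `layer_labels`, `layers` (list of symmetric matrices), `segment_span`,
#'   `normalized`.
#' @export
build_multiplex <- function(segment, span = c(NA_real_, NA_real_)) {
  segment <- check_segment(segment)
  layers <- list(
    AEC = normalize_layer(aec(segment)),
    IPLV = normalize_layer(iplv(segment))
  )
  new_multiplex(layers, span = span, normalized = TRUE)
}

#' @rdname build_multiplex
#' @param layers named list of symmetric weight matrices (one per layer).
#' @param normalized logical; whether the layers are min-max normalized.
#' @export
new_multiplex <- function(layers, span = c(NA_real_, NA_real_),
                          normalized = FALSE) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  n <- nrow(layers[[1]])
  for (l in layers) {
    if (!isTRUE(all.equal(dim(l), c(n, n)))) stop("layer shape mismatch")
    if (max(abs(l - t(l))) > 1e-12) stop("layer matrix not symmetric")
    if (any(diag(l) != 0)) stop("layer diagonal must be 0")
    if (normalized && (min(l) < 0 || max(l) > 1)) {
      stop("normalized layers must lie in [0, 1]")
    }
  }
  if (is.null(names(layers))) {
    names(layers) <- paste0("layer", seq_along(layers))
  }
  structure(
    list(
      n_nodes = n,
      layer_labels = names(layers),
      layers = layers,
      segment_span = span,
      normalized = normalized
    ),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d nodes, layers: %s%s\n",
              x$n_nodes, paste(x$layer_labels, collapse = ", "),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}
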