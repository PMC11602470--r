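#' Segmentation parameters
#'
#' @param reference_window_s reference/candidate window length W_r in seconds
#'   (default 2).
#' @param p_kde upper-tail probability for declaring a network-structure
#'   distance an outlier under the kernel-density estimate of recent
#'   distances (default 0.96).
#' @param step_s advance of the sliding window pair in seconds (default
#'   0.25).
#' @param min_segment_s minimum segment length in seconds (default 0.5).
#' @param max_segment_s forced-split maximum segment length in seconds
#'   (default 10).
#' @param min_history number of observed distances required before outlier
#'   calls are made (default 30).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(reference_window_s = 2, p_kde = 0.96,
                                step_s = 0.25, min_segment_s = 0.5,
                                max_segment_s = 10, min_history = 30L) {
  if (!(p_kde > 0 && p_kde < 1)) stop("p_kde must lie in (0, 1)")
  if (!(min_segment_s <= reference_window_s &&
        reference_window_s <= max_segment_s)) {
    stop("need min_segment_s <= reference_window_s <= max_segment_s")
  }
  if (step_s <= 0) stop("step_s must be positive")
  structure(
    list(reference_window_s = reference_window_s, p_kde = p_kde,
         step_s = step_s, min_segment_s = min_segment_s,
         max_segment_s = max_segment_s, min_history = as.integer(min_history)),
    class = "segmentation_config"
  )
}

new_segmentation <- function(spans, sampling_rate) {
  if (nrow(spans) > 0) {
    stopifnot(all(spans$end > spans$start))
  }
  structure(list(spans = spans, sampling_rate = sampling_rate),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d segments covering %.2f s\n",
              nrow(x$spans), sum(x$spans$end - x$spans$start)))
  invisible(x)
}

#' Distance between two multiplex centrality profiles
#'
#' The Euclidean distance between the layer-averaged closeness-centrality
#' profiles of two time windows:
#' `d = sqrt( sum_i ( mean_l c_i^[l](T1) - mean_l c_i^[l](T2) )^2 )`.
#' This is the quantity the segmenter monitors for change points.
#'
#' @param C1,C2 `centrality_matrix` objects of equal shape.
#' @return Nonnegative scalar.
#' @export
edmcc_distance <- function(C1, C2) {
  stopifnot(inherits(C1, "centrality_matrix"),
            inherits(C2, "centrality_matrix"))
  if (!all(dim(C1$values) == dim(C2$values))) {
    stop("centrality matrices must share shape")
  }
  sqrt(sum((C1$overlapping - C2$overlapping)^2))
}

# Quantile of a Gaussian KDE (Scott's-rule bandwidth) fitted to x.
kde_quantile <- function(x, p) {
  h <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
  if (!is.finite(h) || h <= 0) return(max(x))
  cdf <- function(q) mean(stats::pnorm(q, mean = x, sd = h)) - p
  lo <- min(x) - 6 * h
  hi <- max(x) + 6 * h
  stats::uniroot(cdf, c(lo, hi), tol = h * 1e-4)$root
}

segment_overlapping <- function(data, span, rate, interlayer) {
  net <- build_multiplex(data, span = span)
  centrality_matrix(net, interlayer = interlayer)
}

# Lean computation of the overlapping-closeness profile of one window;
# numerically identical to centrality_matrix(build_multiplex(w))$overlapping
# with the default within-layer convention, but without S3 construction
# overhead (this sits in the segmenter's inner loop).
overlapping_profile <- function(w) {
  a <- analytic_signal(w)
  env <- Mod(a)
  aec_m <- abs(stats::cor(t(env)))
  aec_m[!is.finite(aec_m)] <- 0
  z <- a / ifelse(env == 0, 1, env)
  iplv_m <- abs(Im(z %*% Conj(t(z)))) / ncol(w)
  prof <- 0
  for (m in list(aec_m, iplv_m)) {
    diag(m) <- NA
    r_min <- min(m, na.rm = TRUE)
    r_max <- max(m, na.rm = TRUE)
    if (r_max == r_min) {
      m[] <- 1
    } else {
      m <- (m - r_min) / (r_max - r_min)
    }
    diag(m) <- 0
    prof <- prof + closeness_from_weights(m)
  }
  prof / 2
}

# Contiguous runs of TRUE in a logical mask, as an index matrix.
valid_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment a recording at points of network-structure change
#'
#' Slides a trailing reference window and a leading candidate window (each
#' `reference_window_s` long) along the recording in steps of `step_s`. At
#' each position the distance between the two windows' layer-averaged
#' closeness-centrality profiles ([edmcc_distance()]) is computed and pooled;
#' once at least `min_history` distances have been observed, a boundary is
#' declared at the junction of the two windows whenever the current distance
#' exceeds the `p_kde` quantile of a Gaussian kernel-density estimate of the
#' previously observed distances. Segments are kept within
#' `[min_segment_s, max_segment_s]`; reaching the maximum forces a split.
#' Masked (artifact) stretches break the analysis: each contiguous valid run
#' is segmented independently and runs shorter than two windows yield no
#' segments.
#'
#' @param rec a `banded_recording`.
#' @param cfg a [segmentation_config()].
#' @param interlayer centrality convention, see [overlapping_closeness()].
#' @return A `segmentation` whose `spans` data frame has columns `start`,
#'   `end` in seconds (half-open intervals).
#' @export
segment_recording <- function(rec, cfg = segmentation_config(),
                              interlayer = "within") {
  stopifnot(inherits(rec, "banded_recording"))
  rate <- rec$sampling_rate
  w_n <- round(cfg$reference_window_s * rate)
  step_n <- max(1L, round(cfg$step_s * rate))
  min_n <- round(cfg$min_segment_s * rate)
  max_n <- round(cfg$max_segment_s * rate)
  if (sum(rec$valid_mask) < 2L * w_n) {
    stop("recording too short: need at least two reference windows of valid data")
  }
  runs <- valid_runs(rec$valid_mask)
  spans <- list()
  dist_pool <- numeric(0)
  cache <- new.env(parent = emptyenv())
  prof_at <- function(start) {       # profile of window [start, start + w_n)
    key <- as.character(start)
    p <- cache[[key]]
    if (is.null(p)) {
      w <- rec$data[, start:(start + w_n - 1L), drop = FALSE]
      p <- if (identical(interlayer, "within")) overlapping_profile(w) else
        segment_overlapping(w, c(NA, NA), rate, interlayer)$overlapping
      cache[[key]] <- p
    }
    p
  }
  thr <- Inf
  thr_at <- -1L                      # pool size when threshold last updated
  guard_n <- max(1L, w_n %/% step_n)
  pending <- numeric(0)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, "start"]
    b <- runs[r, "end"] + 1L       # half-open [a, b)
    if (b - a < 2L * w_n) next
    seg_start <- a
    boundaries <- integer(0)
    c_pos <- a + w_n
    exceed_pos <- integer(0)         # current run of above-threshold steps
    exceed_d <- numeric(0)
    flush_run <- function() {        # cut at the run's distance peak
      if (length(exceed_pos) == 0L) return(invisible())
      cut <- exceed_pos[which.max(exceed_d)]
      boundaries <<- c(boundaries, cut)
      seg_start <<- cut
      exceed_pos <<- integer(0)
      exceed_d <<- numeric(0)
      invisible()
    }
    while (c_pos + w_n <= b) {
      diff_p <- prof_at(c_pos - w_n) - prof_at(c_pos)
      d <- sqrt(sum(diff_p^2))
      if (length(dist_pool) >= cfg$min_history &&
          length(dist_pool) - thr_at >= 4L) {
        thr <- kde_quantile(dist_pool, cfg$p_kde)
        thr_at <- length(dist_pool)
      }
      outlier <- length(dist_pool) >= cfg$min_history && d > thr &&
        c_pos - seg_start >= min_n
      # guard gap: a distance joins the null pool only one window length
      # later, so a change plateau cannot inflate the threshold used to
      # detect it
      pending <- c(pending, d)
      if (length(pending) > guard_n) {
        dist_pool <- c(dist_pool, pending[1])
        pending <- pending[-1]
      }
      if (outlier) {
        exceed_pos <- c(exceed_pos, c_pos)
        exceed_d <- c(exceed_d, d)
      } else {
        flush_run()
        if (c_pos - seg_start >= max_n) {   # forced split at maximum length
          boundaries <- c(boundaries, c_pos)
          seg_start <- c_pos
        }
      }
      c_pos <- c_pos + step_n
    }
    flush_run()
    cuts <- c(a, boundaries, b)
    seg <- data.frame(start_i = cuts[-length(cuts)], end_i = cuts[-1])
    # fold a too-short trailing remainder into the previous segment
    n_seg <- nrow(seg)
    if (n_seg >= 2L && seg$end_i[n_seg] - seg$start_i[n_seg] < min_n) {
      seg$end_i[n_seg - 1L] <- seg$end_i[n_seg]
      seg <- seg[-n_seg, , drop = FALSE]
    }
    seg <- seg[seg$end_i - seg$start_i >= min_n, , drop = FALSE]
    if (nrow(seg) > 0) {
      spans[[length(spans) + 1L]] <-
        data.frame(start = (seg$start_i - 1L) / rate, end = (seg$end_i - 1L) / rate)
    }
  }
  spans <- if (length(spans)) do.call(rbind, spans) else
    data.frame(start = numeric(0), end = numeric(0))
  new_segmentation(spans, rate)
}

#' Fixed-length sliding-window segmentation
#'
#' Uniform non-overlapping windows of `length_s` seconds covering each
#' contiguous valid stretch; trailing remainders are dropped. This is the
#' baseline against which structure-driven segmentation is compared.
#'
#' @param rec a `banded_recording`.
#' @param length_s window length in seconds.
#' @return A `segmentation`.
#' @export
sliding_window_segment <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "banded_recording"))
  if (length_s <= 0) stop("length_s must be positive")
  rate <- rec$sampling_rate
  w_n <- round(length_s * rate)
  runs <- valid_runs(rec$valid_mask)
  spans <- list()
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, "start"]
    b <- runs[r, "end"] + 1L
    k <- (b - a) %/% w_n
    if (k < 1L) next
    starts <- a + (seq_len(k) - 1L) * w_n
    spans[[length(spans) + 1L]] <-
      data.frame(start = (starts - 1L) / rate,
                 end = (starts + w_n - 1L) / rate)
  }
  if (!length(spans)) {
    warning("recording shorter than one window: empty segmentation")
    spans <- list(data.frame(start = numeric(0), end = numeric(0)))
  }
  new_segmentation(do.call(rbind, spans), rate)
}

#' Between- versus within-segment structure contrast
#'
#' For each pair of adjacent segments, compares the network-structure
#' distance between the two whole segments against the distance between each
#' segment's first and second half. `p_diff` is the fraction of adjacent
#' pairs for which the between-segment distance strictly exceeds both
#' within-segment distances; a good segmentation places boundaries where
#' structure changes, making that fraction high.
#'
#' @param rec the `banded_recording` the segmentation refers to.
#' @param seg a `segmentation` with at least 2 segments.
#' @param interlayer centrality convention, see [overlapping_closeness()].
#' @return Score in `[0, 1]`, or `NA` (with a warning) for fewer than 2
#'   segments.
#' @export
p_diff <- function(rec, seg, interlayer = "within") {
  stopifnot(inherits(rec, "banded_recording"), inherits(seg, "segmentation"))
  spans <- seg$spans
  if (nrow(spans) < 2L) {
    warning("p_diff needs at least 2 segments")
    return(NA_real_)
  }
  rate <- rec$sampling_rate
  idx <- function(s, e) (round(s * rate) + 1L):(round(e * rate))
  prof <- function(i) {
    segment_overlapping(rec$data[, i, drop = FALSE], c(NA, NA), rate,
                        interlayer)
  }
  whole <- lapply(seq_len(nrow(spans)),
                  function(k) prof(idx(spans$start[k], spans$end[k])))
  within <- vapply(seq_len(nrow(spans)), function(k) {
    i <- idx(spans$start[k], spans$end[k])
    half <- length(i) %/% 2L
    edmcc_distance(prof(i[seq_len(half)]), prof(i[(half + 1L):length(i)]))
  }, numeric(1))
  wins <- 0L
  pairs <- 0L
  for (k in seq_len(nrow(spans) - 1L)) {
    # only compare segments adjacent in time (not across masked gaps)
    if (abs(spans$end[k] - spans$start[k + 1L]) > 1e-9) next
    between <- edmcc_distance(whole[[k]], whole[[k + 1L]])
    pairs <- pairs + 1L
    if (between > within[k] && between > within[k + 1L]) wins <- wins + 1L
  }
  if (pairs == 0L) {
    warning("no adjacent segment pairs")
    return(NA_real_)
  }
  wins / pairs
}
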