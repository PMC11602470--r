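#' Run the synthetic classification benchmark for one participant
#'
#' The package's reference study conditions: one participant with two trials
#' per condition of `duration` seconds, four planted network states shared
#' by both conditions, focused-learning dynamics favoring transitions within
#' states A and B and mind-wandering dynamics favoring C and D
#' (see [benchmark_conditions()]). Each trial is simulated per band,
#' segmented at network-structure change points, and pooled into the
#' state-clustering and sequence-classification stages; the result is the
#' participant's cross-validated detection performance.
#'
#' @param seed integer seed driving every random stage.
#' @param duration trial length in seconds (default 240).
#' @param bands bands to simulate and offer to band selection (default
#'   theta and alpha).
#' @param contrast transition-matrix contrast of the two conditions, see
#'   [benchmark_conditions()].
#' @param identical_conditions if `TRUE`, the mind-wandering condition uses
#'   the focused-learning transition matrix (a null benchmark whose AUC
#'   should hover around 0.5).
#' @param windows_per_fold sub-sequences each held-out block is scored in
#'   (default 2: with roughly ten segments per cross-validation block, two
#'   windows of about five symbols each are long enough to carry a stable
#'   posterior score).
#' @param seg_cfg segmentation parameters.
#' @return List with `result` (a `classification_result`), `catalogs`
#'   (per-band `state_catalog`), and `sequences` (per-band per-condition
#'   symbol sequences).
#' @export
benchmark_classification <- function(seed, duration = 240,
                                     bands = c("theta", "alpha"),
                                     contrast = 0.8,
                                     identical_conditions = FALSE,
                                     windows_per_fold = 2,
                                     seg_cfg = segmentation_config()) {
  bench <- benchmark_conditions(contrast = contrast, seed = 42)
  mw_spec <- if (identical_conditions) {
    condition_spec("MW", bench$fl_spec$state_transition_matrix,
                   dwell_mean = bench$fl_spec$dwell_mean,
                   snr = bench$fl_spec$snr)
  } else {
    bench$mw_spec
  }
  seqs_by_band <- list()
  catalogs <- list()
  for (b in bands) {
    trials <- simulate_participant(
      bench$library, bench$fl_spec, mw_spec,
      n_trials_per_condition = 2, duration = duration, band = b,
      seed = (seed * 17L + match(b, bands)) %% 2147483647L)
    vectors <- NULL
    meta <- NULL
    for (nm in names(trials)) {
      rec <- trials[[nm]]$recording
      seg <- segment_recording(rec, seg_cfg)
      sc <- segment_centralities(rec, seg)
      vectors <- rbind(vectors, sc$vectors)
      meta <- rbind(meta, sc$meta)
    }
    normed <- normalize_centralities(vectors, meta$participant)
    graph <- build_similarity_graph(normed)
    catalog <- detect_states(graph, seed = seed, vectors = normed,
                             durations = meta$duration)
    catalogs[[b]] <- catalog
    meta$state <- as.character(catalog$assignment)
    by_trial <- function(cond) {
      trs <- sort(unique(meta$trial[startsWith(meta$trial, cond)]))
      lapply(trs, function(tr) {
        rows <- meta[meta$trial == tr, ]
        rows$state[order(rows$start)]
      })
    }
    seqs_by_band[[b]] <- list(FL = by_trial("FL"), MW = by_trial("MW"))
  }
  result <- crossvalidate_participant(seqs_by_band, seed = seed,
                                      windows_per_fold = windows_per_fold)
  list(result = result, catalogs = catalogs, sequences = seqs_by_band)
}
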