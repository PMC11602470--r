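#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are kept as
#' strings (callers coerce). Used for pipeline configuration and for array
#' sidecar metadata.
#'
#' @param path file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop(sprintf("malformed config line: '%s'", ln))
    out[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  out
}

cfg_num <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) as.numeric(cfg[[key]]) else default
}

cfg_chr <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

write_table <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes load-or-synthesize, band-pass filtering, amplitude-based
#' artifact rejection, network-structure segmentation, state clustering,
#' sequence dynamics with the permutation test, condition comparisons, and
#' per-participant HMM classification, writing per-stage delimited tables
#' and a log of the effective configuration into the output directory.
#'
#' Recognized keys (defaults in parentheses): `mode` (`synthetic`; or
#' `files` with an `input_manifest` TSV of `path, format, participant,
#' trial, sampling_rate`), `out_dir` (required), `seed` (1), `bands`
#' (`alpha`), `n_participants` (2), `n_trials_per_condition` (2),
#' `duration` (120), `dwell_mean` (2), `contrast` (0.8), `rate` (256),
#' `amplitude_threshold` (100), `artifact_pad` (0.25), `reference_window_s`
#' (2), `p_kde` (0.96), `step_s` (0.25), `min_segment_s` (0.5),
#' `max_segment_s` (10), `resolution` (1), `n_perm` (999), `cv_folds` (8),
#' `windows_per_fold` (4).
#'
#' @param config named list (see [read_config()]) or path to a config file.
#' @return Invisibly, a list with the state catalogs, sequences, dynamics
#'   tables, comparison results, and classification results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  out_dir <- cfg_chr(config, "out_dir")
  if (is.null(out_dir)) stop("missing config keys: out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg_num(config, "seed", 1))
  bands <- strsplit(cfg_chr(config, "bands", "alpha"), ",[ ]*")[[1]]
  mode <- cfg_chr(config, "mode", "synthetic")
  rate <- cfg_num(config, "rate", 256)
  seg_cfg <- segmentation_config(
    reference_window_s = cfg_num(config, "reference_window_s", 2),
    p_kde = cfg_num(config, "p_kde", 0.96),
    step_s = cfg_num(config, "step_s", 0.25),
    min_segment_s = cfg_num(config, "min_segment_s", 0.5),
    max_segment_s = cfg_num(config, "max_segment_s", 10)
  )
  thr <- cfg_num(config, "amplitude_threshold", 100)
  pad <- cfg_num(config, "artifact_pad", 0.25)

  # stage 1: collect banded recordings per participant/trial/band
  recordings <- list()  # keyed participant|trial|band
  if (identical(mode, "synthetic")) {
    n_part <- cfg_num(config, "n_participants", 2)
    bench <- benchmark_conditions(
      dwell_mean = cfg_num(config, "dwell_mean", 2),
      contrast = cfg_num(config, "contrast", 0.8),
      seed = seed)
    for (p in seq_len(n_part)) {
      pid <- sprintf("S%02d", p)
      for (b in bands) {
        trials <- simulate_participant(
          bench$library, bench$fl_spec, bench$mw_spec,
          n_trials_per_condition = cfg_num(config, "n_trials_per_condition", 2),
          duration = cfg_num(config, "duration", 120),
          band = b, rate = rate,
          seed = seed + 193L * p + 7L * match(b, bands),
          participant_id = pid)
        for (tr in names(trials)) {
          recordings[[paste(pid, tr, b, sep = "|")]] <-
            trials[[tr]]$recording
        }
      }
    }
  } else if (identical(mode, "files")) {
    manifest_path <- cfg_chr(config, "input_manifest")
    if (is.null(manifest_path)) stop("missing config keys: input_manifest")
    manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    for (i in seq_len(nrow(manifest))) {
      rec <- load_recording(manifest$path[i], manifest$format[i],
                            sampling_rate = manifest$sampling_rate[i],
                            participant_id = manifest$participant[i],
                            trial_label = manifest$trial[i])
      for (b in bands) {
        recordings[[paste(manifest$participant[i], manifest$trial[i], b,
                          sep = "|")]] <- bandpass_filter(rec, b)
      }
    }
  } else {
    stop(sprintf("unknown mode '%s'", mode))
  }

  # stage 2: artifact rejection, segmentation, per-segment centralities
  feats <- list()
  for (key in names(recordings)) {
    rec <- reject_by_amplitude(recordings[[key]], threshold = thr, pad = pad)
    seg <- segment_recording(rec, seg_cfg)
    feats[[key]] <- segment_centralities(rec, seg)
  }

  # stage 3: per band, pool, normalize, cluster into states
  results <- list()
  seq_tables <- list()
  for (b in bands) {
    keys <- names(feats)[endsWith(names(feats), paste0("|", b))]
    vectors <- do.call(rbind, lapply(keys, function(k) feats[[k]]$vectors))
    meta <- do.call(rbind, lapply(keys, function(k) feats[[k]]$meta))
    normed <- normalize_centralities(vectors, meta$participant)
    graph <- build_similarity_graph(normed)
    catalog <- detect_states(graph, seed = seed,
                             resolution = cfg_num(config, "resolution", 1),
                             vectors = normed, durations = meta$duration)
    meta$state <- as.character(catalog$assignment)

    seqs <- list()
    for (pid in unique(meta$participant)) {
      for (tr in unique(meta$trial[meta$participant == pid])) {
        rows <- meta$participant == pid & meta$trial == tr
        seqs[[paste(pid, tr, sep = "|")]] <- build_state_sequence(
          meta$state[rows], meta$start[rows], meta$end[rows],
          participant_id = pid, trial_label = tr, band = b)
      }
    }
    cond_of <- function(s) sub("-.*$", "", s$trial_label)
    dyn_rows <- lapply(seqs, function(s) {
      m <- sequence_metrics(s, all_states = catalog$state_labels)
      cbind(participant = s$participant_id, trial = s$trial_label,
            band = b, m)
    })
    stats_tests <- list()
    for (cond in c("FL", "MW")) {
      cs <- Filter(function(s) cond_of(s) == cond, seqs)
      has_trans <- vapply(cs, function(s) {
        nrow(s$runs) >= 2L && length(unique(s$runs$state)) >= 2L
      }, logical(1))
      if (any(has_trans)) {
        stats_tests[[cond]] <- suppressWarnings(transition_randomness_test(
          cs[has_trans], n_perm = cfg_num(config, "n_perm", 999),
          seed = seed + match(cond, c("FL", "MW")),
          all_states = catalog$state_labels))
      }
    }
    results[[b]] <- list(catalog = catalog, sequences = seqs,
                         metrics = do.call(rbind, dyn_rows),
                         transition_tests = stats_tests, meta = meta)
    seq_tables[[b]] <- do.call(rbind, lapply(seqs, function(s) {
      data.frame(participant = s$participant_id, trial = s$trial_label,
                 band = b, run = seq_len(nrow(s$runs)),
                 state = s$runs$state, duration = s$runs$duration,
                 stringsAsFactors = FALSE)
    }))
  }

  # stage 4: condition comparison of coverage per state (first band)
  comparisons <- list()
  for (b in bands) {
    m <- results[[b]]$metrics
    for (st in unique(m$state)) {
      rows <- m$state == st
      aa <- m$coverage[rows & startsWith(m$trial, "FL")]
      bb <- m$coverage[rows & startsWith(m$trial, "MW")]
      if (length(aa) >= 4 && length(bb) >= 4) {
        comparisons[[paste(b, st, sep = "|")]] <- suppressWarnings(
          compare_groups(aa, bb, metric = paste0("coverage/", b, "/", st)))
      }
    }
  }

  # stage 5: per-participant HMM classification across bands
  classif <- list()
  participants <- unique(sub("\\|.*$", "", names(recordings)))
  for (pid in participants) {
    # per-segment state labels (time-ordered) are the observation sequences
    seqs_by_band <- lapply(results, function(r) {
      m <- r$meta[r$meta$participant == pid, ]
      by_trial <- function(cond) {
        trials <- sort(unique(m$trial[startsWith(m$trial, cond)]))
        lapply(trials, function(tr) {
          rows <- m[m$trial == tr, ]
          rows$state[order(rows$start)]
        })
      }
      list(FL = by_trial("FL"), MW = by_trial("MW"))
    })
    classif[[pid]] <- tryCatch(
      crossvalidate_participant(
        seqs_by_band, k = cfg_num(config, "cv_folds", 8),
        seed = seed + match(pid, participants),
        windows_per_fold = cfg_num(config, "windows_per_fold", 4),
        participant_id = pid),
      error = function(e) {
        warning(sprintf("classification failed for %s: %s", pid,
                        conditionMessage(e)))
        NULL
      })
  }

  # outputs
  write_table(do.call(rbind, seq_tables), out_dir, "state_sequences")
  write_table(do.call(rbind, lapply(results, `[[`, "metrics")), out_dir,
              "dynamics_metrics")
  if (length(comparisons)) {
    write_table(do.call(rbind, lapply(comparisons, function(x) {
      data.frame(metric = x$metric, test = x$test, statistic = x$statistic,
                 p_value = x$p_value, significant = x$significant)
    })), out_dir, "group_comparisons")
  }
  cls_ok <- Filter(Negate(is.null), classif)
  if (length(cls_ok)) {
    write_table(do.call(rbind, lapply(cls_ok, function(x) {
      data.frame(participant = x$participant_id,
                 auc_mean = x$summary["auc_mean"],
                 auc_sd = x$summary["auc_sd"],
                 f1_mean = x$summary["f1_mean"],
                 f1_sd = x$summary["f1_sd"])
    })), out_dir, "classification")
  }
  log_lines <- c(
    sprintf("mwnetdyn pipeline log (%s)", format(Sys.time())),
    sprintf("seed = %d", seed),
    vapply(names(config), function(k)
      sprintf("%s = %s", k, as.character(config[[k]])), character(1)))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))

  invisible(list(bands = results, comparisons = comparisons,
                 classification = classif))
}
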