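#' Planted multiplex network states
#'
#' A planted state is a connectivity motif: a set of channel pairs that share
#' an amplitude-coupled source (visible to the amplitude-envelope-correlation
#' layer) and a set of pairs that share a phase-lagged source (visible to the
#' imaginary-phase-locking layer). A library of mutually distinct states,
#' switching under condition-specific Markov dynamics, emulates the recurring
#' multilayer network states the pipeline is designed to recover.
#'
#' @param state_id label.
#' @param amp_edges 2-column matrix of channel index pairs with amplitude
#'   coupling.
#' @param phase_edges 2-column matrix of channel index pairs with phase
#'   coupling.
#' @param amp_strength mixing coefficient of the shared sources, in `[0, 1]`.
#' @param phase_lag imposed phase lag in radians, in `(0, pi)`; zero-lag
#'   coupling would be invisible to the imaginary phase-locking value, so the
#'   default pi/4 keeps the imaginary part large.
#' @return A `planted_state` list.
#' @export
planted_state <- function(state_id, amp_edges, phase_edges,
                          amp_strength = 0.9, phase_lag = pi / 4) {
  amp_edges <- as.matrix(amp_edges)
  phase_edges <- as.matrix(phase_edges)
  for (e in list(amp_edges, phase_edges)) {
    if (nrow(e) > 0 && any(e[, 1] == e[, 2])) stop("self-pair in edge set")
  }
  if (amp_strength < 0 || amp_strength > 1) {
    stop("amp_strength must lie in [0, 1]")
  }
  if (!(phase_lag > 0 && phase_lag < pi)) {
    stop("phase_lag must lie in (0, pi)")
  }
  structure(list(state_id = state_id, amp_edges = amp_edges,
                 phase_edges = phase_edges, amp_strength = amp_strength,
                 phase_lag = phase_lag),
            class = "planted_state")
}

# connected components of an undirected edge list, as channel-index vectors
edge_components <- function(e) {
  if (is.null(e) || nrow(e) == 0) return(list())
  nodes <- sort(unique(as.vector(e)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
    v
  }
  for (i in seq_len(nrow(e))) {
    r1 <- find(e[i, 1]); r2 <- find(e[i, 2])
    if (r1 != r2) parent[[as.character(r1)]] <- r2
  }
  roots <- vapply(nodes, find, numeric(1))
  unname(lapply(split(nodes, roots), sort))
}

edge_key <- function(e) {
  if (nrow(e) == 0) return(character(0))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
}

state_edge_set <- function(st) {
  unique(c(edge_key(st$amp_edges), edge_key(st$phase_edges)))
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Generate a library of mutually distinct planted states
#'
#' Each state is a pair of group motifs: a random subset of channels forms
#' an amplitude-coupled group (all pairs within it amplitude-coupled
#' through one shared source) and a disjoint subset forms a phase-coupled
#' group (all pairs phase-coupled with progressive lags). Group coupling is
#' used because it concentrates connectivity — and therefore closeness
#' centrality — on the group's channels, giving each state a recoverable
#' centrality signature. States are redrawn until every pair of states has
#' edge-set Jaccard overlap below 0.5. Deterministic given `seed`.
#'
#' @param n_states number of states (>= 2).
#' @param n_channels number of channels (>= 3).
#' @param seed integer seed.
#' @param amp_strength,phase_lag passed to [planted_state()].
#' @param group_size channels per coupled group (default `n_channels %/% 2`).
#' @return List of `planted_state` objects, with the channel count attached
#'   as attribute `n_channels`.
#' @export
make_state_library <- function(n_states, n_channels, seed,
                               amp_strength = 0.9, phase_lag = pi / 4,
                               group_size = NULL) {
  if (n_states < 2L) stop("need at least 2 states")
  if (n_channels < 3L) stop("need at least 3 channels")
  g <- if (is.null(group_size)) max(2L, n_channels %/% 2L) else
    as.integer(group_size)          # default: 4 + 4 on the 8-channel montage
  clique <- function(v) t(utils::combn(sort(v), 2))
  rng <- local_rng(seed)
  states <- list()
  attempts <- 0L
  while (length(states) < n_states) {
    attempts <- attempts + 1L
    if (attempts > 2000L) {
      stop("cannot draw mutually distinct edge sets: too few channels")
    }
    perm <- rng$sample(n_channels, n_channels)
    amp_group <- perm[seq_len(max(2L, min(g, n_channels - 2L)))]
    rest <- perm[(length(amp_group) + 1L):n_channels]
    phase_group <- rest[seq_len(min(g, length(rest)))]
    if (length(phase_group) < 2L) {      # tiny montages: share one channel
      phase_group <- c(phase_group, amp_group[1L])
    }
    cand <- planted_state(LETTERS[length(states) + 1L],
                          clique(amp_group), clique(phase_group),
                          amp_strength = amp_strength, phase_lag = phase_lag)
    ok <- all(vapply(states, function(s) {
      jaccard(state_edge_set(s), state_edge_set(cand)) < 0.5
    }, logical(1)))
    if (ok) states[[length(states) + 1L]] <- cand
  }
  attr(states, "n_channels") <- as.integer(n_channels)
  states
}

#' Condition specification for the generator
#'
#' @param condition `"FL"` (focused learning) or `"MW"` (mind-wandering).
#' @param state_transition_matrix row-stochastic matrix over the planted
#'   states of the library.
#' @param dwell_mean mean state dwell time in seconds (exponential dwell).
#' @param snr amplitude ratio of the coupled sources relative to the
#'   independent background (1 = equal).
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(condition = c("FL", "MW"), state_transition_matrix,
                           dwell_mean = 2, snr = 1) {
  condition <- match.arg(condition)
  m <- as.matrix(state_transition_matrix)
  if (nrow(m) != ncol(m)) stop("transition matrix must be square")
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  if (any(m < 0)) stop("transition probabilities must be nonnegative")
  if (dwell_mean <= 0) stop("dwell_mean must be positive")
  structure(list(condition = condition, state_transition_matrix = m,
                 dwell_mean = dwell_mean, snr = snr),
            class = "condition_spec")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# Self-contained RNG stream so generator draws cannot disturb (or be
# disturbed by) the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    rnorm = function(n) with_state(stats::rnorm(n)),
    runif = function(n) with_state(stats::runif(n)),
    rexp = function(n, rate = 1) with_state(stats::rexp(n, rate)),
    sample = function(x, size, prob = NULL) with_state(sample(x, size, prob = prob)),
    int = function() with_state(sample.int(.Machine$integer.max, 1L))
  )
}

# Unit-variance narrowband noise: white noise shaped by the pipeline's own
# FIR band-pass (zero-phase magnitude-squared response, applied in the
# frequency domain), so generated signals are spectrally compatible with
# the analysis filters.
narrowband_noise <- function(n, band_edges, rate, rng) {
  taps <- fir_bandpass_taps(band_edges[1], band_edges[2], rate)
  if (length(taps) >= n) {           # very short windows: time-domain path
    x <- filtfilt_fir(taps, rng$rnorm(n))
    return(x / stats::sd(x))
  }
  h2 <- Mod(stats::fft(c(taps, numeric(n - length(taps)))))^2
  x <- Re(stats::fft(stats::fft(rng$rnorm(n)) * h2, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slowly varying positive envelope in [0.2, 1.8] (lowpass noise through tanh).
slow_envelope <- function(n, rate, rng, cutoff_hz = 0.4) {
  bf <- signal::butter(2, min(0.9, cutoff_hz / (rate / 2)), type = "low")
  z <- signal::filtfilt(bf, rng$rnorm(n))
  1 + 0.8 * tanh(z / stats::sd(z))
}

# Fractional-sample delay via FFT phase rotation.
frac_delay <- function(x, tau_s, rate) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / n * rate
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * tau_s), inverse = TRUE)) / n
}

# Draw a Markov state path with exponential dwell times covering `duration`.
draw_state_path <- function(spec, n_states, duration, rng) {
  cur <- rng$sample(n_states, 1L)
  onsets <- numeric(0)
  states <- integer(0)
  t <- 0
  while (t < duration) {
    onsets <- c(onsets, t)
    states <- c(states, cur)
    t <- t + rng$rexp(1L, rate = 1 / spec$dwell_mean)
    cur <- rng$sample(n_states, 1L,
                      prob = spec$state_transition_matrix[cur, ])
  }
  data.frame(onset = onsets, offset = c(onsets[-1], duration),
             state = states)
}

#' Simulate one band-limited trial with planted switching connectivity
#'
#' Draws a hidden state path from the condition's Markov chain with
#' exponential dwell times, then synthesizes an `n_channels`-channel signal:
#' every channel carries independent narrowband noise; while a state is
#' active, each of its amplitude-coupled pairs additionally shares an
#' envelope-modulated narrowband source (zero lag, so it raises envelope
#' correlation but not imaginary phase locking), and each phase-coupled pair
#' shares a narrowband source whose second copy is delayed to impose
#' `phase_lag` at the band's center frequency. Coupled sources are mixed at
#' `amp_strength` (scaled by `sqrt(snr)`) against `sqrt(1 - amp_strength^2)`
#' of independent noise.
#'
#' @param library list of [planted_state()] objects.
#' @param spec a [condition_spec()].
#' @param duration trial length in seconds (>= 10).
#' @param band band name.
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @param channel_names optional labels (defaults to the 8-channel montage
#'   F3, F4, T3, C3, C4, T4, O1, O2 when the channel count matches).
#' @param participant_id,trial_label metadata for the recording.
#' @param path optional fixed state path (data frame with `onset`, `offset`
#'   seconds and `state` indices into `library`), overriding the Markov
#'   draw; used to plant switches at known times.
#' @return List with `recording` (a `banded_recording`) and `truth`
#'   (data frame of state onsets/offsets plus the change-point times).
#' @export
simulate_trial <- function(library, spec, duration, band, rate = 256, seed = 1,
                           channel_names = NULL, participant_id = "S01",
                           trial_label = "FL-1", path = NULL) {
  if (duration < 10) stop("duration must be at least 10 s")
  if (duration < 2 * spec$dwell_mean) {
    warning("duration below 2 dwell times: too few switches for dynamics")
  }
  bands <- band_table()
  if (!band %in% names(bands)) stop(sprintf("unknown band '%s'", band))
  edges <- bands[[band]]
  n_channels <- attr(library, "n_channels")
  if (is.null(n_channels)) {
    n_channels <- max(vapply(library, function(s) {
      m <- rbind(s$amp_edges, s$phase_edges)
      if (nrow(m) == 0) 0L else max(m)
    }, numeric(1)), 3)
  }
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 8L) {
      c("F3", "F4", "T3", "C3", "C4", "T4", "O1", "O2")
    } else {
      paste0("ch", seq_len(n_channels))
    }
  }
  n <- round(duration * rate)
  rng <- local_rng(seed)
  if (is.null(path)) {
    path <- draw_state_path(spec, length(library), duration, rng)
  }

  x <- matrix(0, nrow = n_channels, ncol = n)
  indep <- t(vapply(seq_len(n_channels),
                    function(ch) narrowband_noise(n, edges, rate, rng),
                    numeric(n)))
  coupled_share <- matrix(0, nrow = n_channels, ncol = n) # per-sample coupled amp
  f_center <- mean(edges)
  for (si in seq_along(library)) {
    st <- library[[si]]
    active <- rep(FALSE, n)
    for (r in which(path$state == si)) {
      i0 <- floor(path$onset[r] * rate) + 1L
      i1 <- min(n, ceiling(path$offset[r] * rate))
      active[i0:i1] <- TRUE
    }
    if (!any(active)) next
    a <- st$amp_strength * sqrt(spec$snr)
    # each connected component of an edge set shares ONE source, so that
    # coupling strength is not diluted when a channel sits in several edges
    # of the same motif (e.g. clique or star motifs)
    for (comp in edge_components(st$amp_edges)) {
      src <- narrowband_noise(n, edges, rate, rng) *
        slow_envelope(n, rate, rng)
      src <- src / stats::sd(src)
      for (ch in comp) {
        x[ch, active] <- x[ch, active] + a * src[active]
        coupled_share[ch, active] <- coupled_share[ch, active] + a
      }
    }
    tau <- st$phase_lag / (2 * pi * f_center)
    for (comp in edge_components(st$phase_edges)) {
      src <- narrowband_noise(n, edges, rate, rng)
      # progressive lags 0, tau, 2*tau, ... along the component, so every
      # within-component pair has a nonzero relative lag below pi
      for (k in seq_along(comp)) {
        lagged <- if (k == 1L) src else frac_delay(src, (k - 1L) * tau, rate)
        ch <- comp[k]
        x[ch, active] <- x[ch, active] + a * lagged[active]
        coupled_share[ch, active] <- coupled_share[ch, active] + a
      }
    }
  }
  # unit-power mixture: coupled amplitude a*sqrt(snr) against sqrt(1 - a^2)
  # of independent noise, renormalized so total power stays near 1
  base_noise <- vapply(seq_len(n_channels), function(ch) {
    shares <- coupled_share[ch, ]
    a0 <- max(shares) / max(sqrt(spec$snr), 1e-12)
    sqrt(max(0, 1 - min(a0, 1)^2))
  }, numeric(1))
  noise_amp <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    noise_amp[ch, ] <- ifelse(coupled_share[ch, ] > 0, base_noise[ch], 1)
  }
  total <- sqrt(coupled_share^2 + noise_amp^2)
  x <- (x + noise_amp * indep) / total
  rec <- new_recording(x, rate, channel_names,
                       participant_id = participant_id,
                       trial_label = trial_label)
  rec <- new_banded_recording(rec, band)
  truth <- path
  truth$state_id <- vapply(library, `[[`, character(1), "state_id")[path$state]
  list(recording = rec, truth = truth,
       change_points = path$onset[-1])
}

#' Simulate all trials of one participant
#'
#' Produces `n_trials_per_condition` trials per condition, labeled
#' `FL-1 ... FL-k` and `MW-1 ... MW-k`, with per-trial seeds derived
#' deterministically from the master seed.
#'
#' @param library list of [planted_state()] objects shared by both
#'   conditions.
#' @param fl_spec,mw_spec [condition_spec()] objects for the two conditions.
#' @param n_trials_per_condition trials per condition (>= 1).
#' @param duration trial length in seconds.
#' @param band band name.
#' @param rate sampling rate in Hz.
#' @param seed master seed.
#' @param participant_id metadata label.
#' @return List of [simulate_trial()] results, named by trial label.
#' @export
simulate_participant <- function(library, fl_spec, mw_spec,
                                 n_trials_per_condition = 2, duration = 120,
                                 band = "alpha", rate = 256, seed = 1,
                                 participant_id = "S01") {
  if (n_trials_per_condition < 1L) stop("need at least 1 trial per condition")
  out <- list()
  idx <- 0L
  for (spec in list(fl_spec, mw_spec)) {
    for (k in seq_len(n_trials_per_condition)) {
      idx <- idx + 1L
      label <- sprintf("%s-%d", spec$condition, k)
      out[[label]] <- simulate_trial(
        library, spec, duration, band, rate,
        seed = (seed * 131L + idx * 7919L) %% 2147483647L,
        participant_id = participant_id, trial_label = label)
    }
  }
  out
}

#' Canonical benchmark conditions
#'
#' The synthetic benchmark used throughout the test suite: a library of four
#' planted states over the 8-channel montage, with a focused-learning
#' condition whose Markov chain favors transitions within states A and B and
#' a mind-wandering condition favoring C and D. Both conditions share the
#' same state library (the same motifs exist in both), differing only in
#' their transition dynamics, and dwell times average 2 s.
#'
#' @param dwell_mean mean dwell in seconds.
#' @param contrast probability mass the favored partner state receives
#'   (default 0.8); `contrast = 1/3` with a uniform matrix makes the two
#'   conditions identical.
#' @param seed seed for the state library.
#' @return List with `library`, `fl_spec`, `mw_spec`.
#' @export
benchmark_conditions <- function(dwell_mean = 2, contrast = 0.8, seed = 42) {
  library <- make_state_library(4, 8, seed = seed)
  favor <- function(pairs) {
    m <- matrix((1 - contrast) / 2, 4, 4)
    diag(m) <- 0
    for (p in pairs) m[p[1], p[2]] <- contrast
    m / rowSums(m)
  }
  fl <- favor(list(c(1, 2), c(2, 1), c(3, 1), c(4, 2)))
  mw <- favor(list(c(3, 4), c(4, 3), c(1, 3), c(2, 4)))
  list(
    library = library,
    fl_spec = condition_spec("FL", fl, dwell_mean = dwell_mean, snr = 2),
    mw_spec = condition_spec("MW", mw, dwell_mean = dwell_mean, snr = 2)
  )
}
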