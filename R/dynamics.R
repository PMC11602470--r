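#' Consolidated state sequence for one trial and band
#'
#' Adjacent segments sharing a state are merged into single runs; masked
#' gaps between segments break runs without creating a transition across
#' the gap.
#'
#' @param states state label per segment (character or factor).
#' @param starts,ends segment spans in seconds, time-ordered and
#'   non-overlapping.
#' @param participant_id,trial_label,band metadata.
#' @return A `state_sequence`: `runs` (data frame `state`, `duration`),
#'   `total_duration`, plus the metadata fields. A `gap` column marks runs
#'   that start after a gap (no transition counted into them).
#' @export
build_state_sequence <- function(states, starts, ends,
                                 participant_id = NA, trial_label = NA,
                                 band = NA) {
  states <- as.character(states)
  n <- length(states)
  stopifnot(length(starts) == n, length(ends) == n)
  if (n == 0L) stop("no segments")
  ord <- order(starts)
  states <- states[ord]; starts <- starts[ord]; ends <- ends[ord]
  if (any(ends <= starts)) stop("segment with nonpositive duration")
  if (n > 1L && any(starts[-1] < ends[-n] - 1e-9)) {
    stop("overlapping segments")
  }
  gap_before <- c(FALSE, starts[-1] > ends[-n] + 1e-9)
  run_state <- character(0)
  run_dur <- numeric(0)
  run_gap <- logical(0)
  for (k in seq_len(n)) {
    new_run <- k == 1L || gap_before[k] ||
      states[k] != run_state[length(run_state)]
    if (new_run) {
      run_state <- c(run_state, states[k])
      run_dur <- c(run_dur, ends[k] - starts[k])
      run_gap <- c(run_gap, if (k == 1L) TRUE else gap_before[k])
    } else {
      run_dur[length(run_dur)] <- run_dur[length(run_dur)] +
        (ends[k] - starts[k])
    }
  }
  structure(
    list(participant_id = participant_id, trial_label = trial_label,
         band = band,
         runs = data.frame(state = run_state, duration = run_dur,
                           after_gap = run_gap, stringsAsFactors = FALSE),
         total_duration = sum(run_dur)),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %s/%s/%s: %d runs, %.2f s\n",
              x$participant_id, x$trial_label, x$band,
              nrow(x$runs), x$total_duration))
  invisible(x)
}

#' Per-state dynamics metrics of a state sequence
#'
#' Frequency is occurrences per second, average duration the mean run length
#' in seconds, coverage the time fraction. States named in `all_states` but
#' absent from the sequence get frequency 0, coverage 0, duration `NA`.
#'
#' @param seq a `state_sequence`.
#' @param all_states optional full state alphabet.
#' @return Data frame with columns `state`, `frequency`, `mean_duration`,
#'   `coverage`.
#' @export
sequence_metrics <- function(seq, all_states = NULL) {
  stopifnot(inherits(seq, "state_sequence"))
  if (seq$total_duration <= 0) stop("total duration must be positive")
  runs <- seq$runs
  if (is.null(all_states)) all_states <- sort(unique(runs$state))
  out <- data.frame(state = all_states, frequency = 0, mean_duration = NA_real_,
                    coverage = 0, stringsAsFactors = FALSE)
  for (i in seq_along(all_states)) {
    s <- all_states[i]
    r <- runs$duration[runs$state == s]
    if (length(r) > 0) {
      out$frequency[i] <- length(r) / seq$total_duration
      out$mean_duration[i] <- mean(r)
      out$coverage[i] <- sum(r) / seq$total_duration
    }
  }
  out
}

# Ordered run-adjacency pairs within a sequence (or list of sequences),
# never across masked gaps or across sequences.
transition_pairs <- function(seqs) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  from <- character(0); to <- character(0)
  for (s in seqs) {
    runs <- s$runs
    if (nrow(runs) < 2L) next
    for (k in 2:nrow(runs)) {
      if (runs$after_gap[k]) next
      from <- c(from, runs$state[k - 1L])
      to <- c(to, runs$state[k])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Observed transition probabilities
#'
#' `P_{X->Y}` is the count of X-to-Y run adjacencies divided by the total
#' number of transitions. Consolidation makes self-transitions impossible,
#' so the diagonal is structurally zero, and the entries sum to 1 over all
#' ordered pairs.
#'
#' @param seqs a `state_sequence` or list of them (pooled).
#' @param all_states optional full state alphabet.
#' @return Square matrix, or `NA` matrix (with a warning) if there are no
#'   transitions.
#' @export
observed_transitions <- function(seqs, all_states = NULL) {
  tp <- transition_pairs(seqs)
  if (is.null(all_states)) {
    all_states <- sort(unique(unlist(lapply(
      if (inherits(seqs, "state_sequence")) list(seqs) else seqs,
      function(s) s$runs$state))))
  }
  k <- length(all_states)
  m <- matrix(0, k, k, dimnames = list(all_states, all_states))
  if (nrow(tp) == 0L) {
    warning("no transitions observed")
    m[] <- NA_real_
    return(m)
  }
  for (i in seq_len(nrow(tp))) {
    m[tp$from[i], tp$to[i]] <- m[tp$from[i], tp$to[i]] + 1
  }
  m / sum(m)
}

#' Frequency-expected transition probabilities
#'
#' Under the null of no sequential structure, the expected probability of an
#' X-to-Y transition is `P*_{X->Y} = P_Y * P_X / (1 - P_X)`, where `P_X` is
#' the fraction of run occurrences that are state X. The rows satisfy
#' `sum_{Y != X} P*_{X->Y} = P_X` and the grand total is 1.
#'
#' @param seqs a `state_sequence` or list of them (pooled).
#' @param all_states optional full state alphabet.
#' @return Square matrix with zero diagonal, or `NA` matrix (with a warning)
#'   for a single-state sequence.
#' @export
expected_transitions <- function(seqs, all_states = NULL) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  occ <- unlist(lapply(seqs, function(s) s$runs$state))
  if (is.null(all_states)) all_states <- sort(unique(occ))
  k <- length(all_states)
  p <- vapply(all_states, function(s) mean(occ == s), numeric(1))
  m <- matrix(NA_real_, k, k, dimnames = list(all_states, all_states))
  if (any(p >= 1)) {
    warning("single-state sequence: expected transitions undefined")
    return(m)
  }
  for (x in seq_len(k)) {
    for (y in seq_len(k)) {
      m[x, y] <- if (x == y) 0 else p[y] * p[x] / (1 - p[x])
    }
  }
  m
}

#' Chi-square distance between transition-probability matrices
#'
#' `d = sum_{X != Y} (P_{X->Y} - P*_{X->Y})^2 / P*_{X->Y}` over off-diagonal
#' cells. Cells where both entries are 0 are skipped; an expected 0 against
#' a positive observation is an error.
#'
#' @param observed,expected square matrices of matching shape.
#' @return Nonnegative scalar.
#' @export
chi_square_distance <- function(observed, expected) {
  if (!all(dim(observed) == dim(expected))) stop("shape mismatch")
  off <- row(observed) != col(observed)
  o <- observed[off]
  e <- expected[off]
  if (any(e == 0 & o > 0)) {
    stop("expected probability 0 with positive observation")
  }
  keep <- !(e == 0 & o == 0)
  sum((o[keep] - e[keep])^2 / e[keep])
}

#' Randomization test for non-random transition structure
#'
#' Tests whether the observed transition probabilities carry sequential
#' structure beyond what state frequencies alone explain. The condition's
#' trials are pooled: the observed and frequency-expected transition
#' matrices are averaged over sequences and compared by the chi-square
#' distance. The null distribution is built by regenerating each trial's
#' run sequence `n_perm` times from the frequency-matched memoryless chain
#' (next state drawn from the pooled run frequencies excluding the current
#' state, which is exactly the process whose transition probabilities are
#' the expectation matrix) and recomputing the distance. The p-value is
#' `(m + 1) / (n_perm + 1)` with `m` the count of null distances greater
#' than or equal to the actual one (tie-inclusive, so observed == expected
#' gives p = 1 rather than 0).
#'
#' @param seqs a `state_sequence` or list of them (one condition's trials).
#' @param n_perm number of null draws (>= 100; default 9999).
#' @param seed integer seed.
#' @param all_states optional full state alphabet.
#' @return A `transition_stats` list: `observed`, `expected` (averages over
#'   sequences), `chi_square_d`, `p_value`, `n_permutations`.
#' @export
transition_randomness_test <- function(seqs, n_perm = 9999, seed = 1,
                                       all_states = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  occ <- unlist(lapply(seqs, function(s) s$runs$state))
  if (is.null(all_states)) all_states <- sort(unique(occ))
  k <- length(all_states)
  obs_list <- lapply(seqs, observed_transitions, all_states = all_states)
  exp_list <- lapply(seqs, expected_transitions, all_states = all_states)
  usable <- !vapply(obs_list, anyNA, logical(1)) &
    !vapply(exp_list, anyNA, logical(1))
  if (!any(usable)) stop("no sequence with defined transition matrices")
  observed_avg <- Reduce(`+`, obs_list[usable]) / sum(usable)
  expected_avg <- Reduce(`+`, exp_list[usable]) / sum(usable)
  d_actual <- chi_square_distance(observed_avg, expected_avg)
  if (k < 2L) {
    warning("single-state alphabet: p = 1")
    return(new_transition_stats(observed_avg, expected_avg, d_actual, 1,
                                n_perm))
  }
  phat <- vapply(all_states, function(s) mean(occ == s), numeric(1))
  run_counts <- vapply(seqs[usable], function(s) nrow(s$runs), integer(1))
  m <- with_seed(seed, null_chain_exceedances(phat, as.integer(run_counts),
                                              as.integer(n_perm), d_actual))
  p <- (m + 1) / (n_perm + 1)
  new_transition_stats(observed_avg, expected_avg, d_actual, p, n_perm)
}

new_transition_stats <- function(observed, expected, d, p, n_perm) {
  structure(
    list(observed = observed, expected = expected, chi_square_d = d,
         p_value = p, n_permutations = n_perm),
    class = "transition_stats"
  )
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("<transition_stats> d = %.4g, p = %.4g (%d permutations)\n",
              x$chi_square_d, x$p_value, x$n_permutations))
  invisible(x)
}
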