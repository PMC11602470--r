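#' Fit a discrete-observation hidden Markov model by Baum-Welch
#'
#' Trains a hidden Markov model with `n_hidden` hidden states on a single
#' categorical sequence via expectation-maximization. Initialization is
#' uniform with a small seeded perturbation (magnitude `perturb`) of every
#' row of the transition and emission matrices: exactly uniform starting
#' values are an EM fixed point with interchangeable hidden states, so the
#' perturbation is what makes training non-degenerate while staying as close
#' as possible to an uninformative start.
#'
#' @param sequence integer vector of observation symbols in `1..n_obs`
#'   (factors and characters are mapped through `sort(unique())`).
#' @param n_hidden number of hidden states (default 2).
#' @param n_obs observation alphabet size (default: maximum observed
#'   symbol).
#' @param seed integer seed for the initialization perturbation.
#' @param tol stop when the log-likelihood gain falls below this (default
#'   1e-4).
#' @param max_iter maximum EM iterations (default 100).
#' @param condition optional condition tag (`"FL"`/`"MW"`) stored on the
#'   model.
#' @param perturb perturbation magnitude (default 0.05).
#' @param n_restarts number of seeded restarts; the fit with the best final
#'   log-likelihood is kept (default 5). EM on discrete HMMs has saddle
#'   points and local optima, and multi-start is the standard defense.
#' @return An `hmm_model`: `A`, `B`, `pi`, `n_hidden`, `n_obs`,
#'   `condition`, `train_log_likelihood_trace` (of the selected restart).
#' @export
fit_hmm <- function(sequence, n_hidden = 2, n_obs = NULL, seed = 1,
                    tol = 1e-4, max_iter = 100, condition = NA_character_,
                    perturb = 0.05, n_restarts = 5) {
  sequence <- as_symbols(sequence)
  if (length(sequence) < 10L) stop("sequence must have at least 10 symbols")
  if (is.null(n_obs)) n_obs <- max(sequence)
  if (n_obs < 2L) stop("alphabet size must be at least 2")
  if (any(sequence > n_obs)) {
    stop("sequence contains symbols outside the alphabet")
  }
  obs0 <- as.integer(sequence) - 1L
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rng <- local_rng(seed + (r - 1L) * 104729L)
    ruffle <- function(nr, nc) {
      m <- matrix(1 / nc, nr, nc) +
        perturb * matrix(rng$runif(nr * nc) - 0.5, nr, nc)
      m <- pmax(m, 1e-6)
      m / rowSums(m)
    }
    A0 <- ruffle(n_hidden, n_hidden)
    B0 <- ruffle(n_hidden, n_obs)
    pi0 <- rep(1 / n_hidden, n_hidden)
    fit <- hmm_baum_welch_cpp(A0, B0, pi0, obs0, tol, as.integer(max_iter))
    ll <- utils::tail(fit$loglik_trace, 1)
    if (is.null(best) || (is.finite(ll) && ll > best$ll)) {
      best <- list(fit = fit, ll = ll)
    }
  }
  fit <- best$fit
  # floor emission probabilities so symbols absent from the training
  # sequence keep a tiny likelihood instead of annihilating test scores
  fit$B <- pmax(fit$B, 1e-8)
  fit$B <- fit$B / rowSums(fit$B)
  structure(
    list(n_hidden = n_hidden, n_obs = n_obs, A = fit$A, B = fit$B,
         pi = as.numeric(fit$pi), condition = condition,
         train_log_likelihood_trace = as.numeric(fit$loglik_trace)),
    class = "hmm_model"
  )
}

as_symbols <- function(sequence) {
  if (is.factor(sequence)) return(as.integer(sequence))
  if (is.character(sequence)) {
    return(match(sequence, sort(unique(sequence))))
  }
  s <- as.integer(sequence)
  if (any(is.na(s)) || any(s < 1L)) stop("symbols must be positive integers")
  s
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model>%s %d hidden states, %d symbols, %d EM iterations\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n_hidden, x$n_obs, length(x$train_log_likelihood_trace)))
  invisible(x)
}

#' Log-likelihood of a sequence under an HMM
#'
#' Scaled forward recursion; finite for any sequence the model assigns
#' nonzero probability.
#'
#' @param model an `hmm_model`.
#' @param sequence integer observation sequence.
#' @return `log P(O | model)`.
#' @export
forward_likelihood <- function(model, sequence) {
  stopifnot(inherits(model, "hmm_model"))
  sequence <- as_symbols(sequence)
  if (length(sequence) == 0L) stop("empty sequence")
  if (any(sequence > model$n_obs)) {
    stop("sequence contains symbols outside the model alphabet")
  }
  hmm_forward_cpp(model$A, model$B, model$pi, as.integer(sequence) - 1L)
}

#' Posterior score for the focused-learning condition
#'
#' Under equal priors, `S_FL = P(Y | FL model) / (P(Y | FL model) +
#' P(Y | MW model))`, computed stably from the log-likelihood difference.
#'
#' @param sequence integer observation sequence.
#' @param model_fl,model_mw the two condition HMMs (shared alphabet).
#' @return Score in `[0, 1]`, or `NA` (with a warning) if both likelihoods
#'   vanish.
#' @export
score_fl <- function(sequence, model_fl, model_mw) {
  if (model_fl$n_obs != model_mw$n_obs) {
    stop("models must share the observation alphabet")
  }
  ll_fl <- forward_likelihood(model_fl, sequence)
  ll_mw <- forward_likelihood(model_mw, sequence)
  if (!is.finite(ll_fl) && !is.finite(ll_mw)) {
    warning("both likelihoods vanish: score undefined")
    return(NA_real_)
  }
  if (!is.finite(ll_fl)) return(0)
  if (!is.finite(ll_mw)) return(1)
  1 / (1 + exp(ll_mw - ll_fl))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties contributing one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) {
    warning("dropping items with undefined scores")
    labels <- labels[!is.na(scores)]
    scores <- scores[!is.na(scores)]
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    warning("both classes required for AUC")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden-optimal threshold: maximizes TPR - FPR over the candidate
# thresholds given by the observed scores (prediction: score >= threshold).
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(thr) {
    pred <- scores >= thr
    tpr <- sum(pred & labels) / max(1, sum(labels))
    fpr <- sum(pred & !labels) / max(1, sum(!labels))
    tpr - fpr
  }, numeric(1))
  cand[which.max(j)]
}

f1_score <- function(pred, labels) {
  tp <- sum(pred & labels)
  if (tp == 0L) return(0)
  precision <- tp / sum(pred)
  recall <- tp / sum(labels)
  2 * precision * recall / (precision + recall)
}

# Split a vector into k contiguous blocks of near-equal length.
split_blocks <- function(x, k) {
  n <- length(x)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(k), function(i) if (sizes[i] > 0L) x[starts[i]:ends[i]] else integer(0))
}

# Score the windows of one test block under both condition models.
score_windows <- function(block, windows_per_fold, model_fl, model_mw) {
  wins <- split_blocks(block, windows_per_fold)
  wins <- wins[vapply(wins, length, integer(1)) > 0L]
  vapply(wins, score_fl, numeric(1), model_fl = model_fl, model_mw = model_mw)
}

# Fit both condition HMMs and compute an AUC on held-out blocks; shared by
# the inner (band-selection) and outer CV loops. Returns NA when any piece
# is too short to train on.
cv_auc <- function(train_fl, train_mw, test_fl, test_mw, n_obs,
                   windows_per_fold, seed) {
  if (length(train_fl) < 10L || length(train_mw) < 10L ||
      length(test_fl) < 1L || length(test_mw) < 1L) {
    return(list(auc = NA_real_, models = NULL))
  }
  m_fl <- fit_hmm(train_fl, n_obs = n_obs, seed = seed, condition = "FL")
  m_mw <- fit_hmm(train_mw, n_obs = n_obs, seed = seed + 1L,
                  condition = "MW")
  s_fl <- score_windows(test_fl, windows_per_fold, m_fl, m_mw)
  s_mw <- score_windows(test_mw, windows_per_fold, m_fl, m_mw)
  scores <- c(s_fl, s_mw)
  labels <- c(rep(TRUE, length(s_fl)), rep(FALSE, length(s_mw)))
  auc <- suppressWarnings(roc_auc(scores, labels))
  list(auc = auc, models = list(fl = m_fl, mw = m_mw))
}

#' Per-participant cross-validated mind-wandering detection
#'
#' For each band, the participant's trial sequences are concatenated per
#' condition and split into `k` contiguous blocks. In every fold, the two
#' condition HMMs are trained on the remaining `k - 1` blocks; the analysis
#' band is chosen by an inner cross-validation on those training blocks
#' only (ties broken toward the lower-frequency band); each held-out block
#' is split into `windows_per_fold` sub-sequences, every window is scored
#' with the posterior FL score, and the fold's AUC is computed over the
#' scored windows. The F1 score (mind-wandering as the positive class) uses
#' the Youden-optimal threshold of the training-window ROC. Band choice and
#' threshold therefore never see test data.
#'
#' @param sequences named list by band (in low-to-high frequency order);
#'   each element a list with components `FL` and `MW`, each a list of
#'   per-trial symbol sequences over the shared state alphabet.
#' @param k number of folds (default 8).
#' @param seed integer seed.
#' @param windows_per_fold sub-sequences each held-out block is split into
#'   (default 4).
#' @param n_obs observation alphabet size (default: maximum symbol across
#'   all sequences).
#' @param inner_k folds of the band-selection inner cross-validation
#'   (default 4).
#' @param participant_id metadata label.
#' @return A `classification_result`: per-fold data frame (`fold`, `band`,
#'   `auc`, `f1`) and `summary` (mean and sd of AUC and F1).
#' @export
crossvalidate_participant <- function(sequences, k = 8, seed = 1,
                                      windows_per_fold = 4, n_obs = NULL,
                                      inner_k = 4,
                                      participant_id = NA_character_) {
  bands <- names(sequences)
  if (is.null(bands)) stop("sequences must be a named list by band")
  # map state labels to integer symbols against one global alphabet, so the
  # two conditions and all bands share the observation coding
  raw <- unlist(lapply(sequences, function(bnd) {
    lapply(c(bnd$FL, bnd$MW), as.character)
  }))
  alphabet <- sort(unique(raw))
  to_sym <- function(trials) {
    if (!is.list(trials)) trials <- list(trials)
    unlist(lapply(trials, function(tr) match(as.character(tr), alphabet)))
  }
  concat <- lapply(sequences, function(bnd) {
    list(FL = to_sym(bnd$FL), MW = to_sym(bnd$MW))
  })
  if (is.null(n_obs)) {
    n_obs <- max(unlist(lapply(concat, function(b) c(b$FL, b$MW))))
  }
  blocks <- lapply(concat, function(b) {
    list(FL = split_blocks(b$FL, k), MW = split_blocks(b$MW, k))
  })
  fold_rows <- list()
  for (f in seq_len(k)) {
    fold_seed <- seed * 1000L + f
    # band selection: inner CV on the training blocks only
    band_scores <- vapply(bands, function(bnd) {
      tr_fl <- unlist(blocks[[bnd]]$FL[-f])
      tr_mw <- unlist(blocks[[bnd]]$MW[-f])
      if (length(tr_fl) < inner_k || length(tr_mw) < inner_k) {
        return(NA_real_)
      }
      in_fl <- split_blocks(tr_fl, inner_k)
      in_mw <- split_blocks(tr_mw, inner_k)
      aucs <- vapply(seq_len(inner_k), function(g) {
        cv_auc(unlist(in_fl[-g]), unlist(in_mw[-g]), in_fl[[g]], in_mw[[g]],
               n_obs, windows_per_fold, fold_seed + 10L * g)$auc
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(band_scores))) {
      warning(sprintf("fold %d skipped: insufficient data", f))
      next
    }
    best <- which(band_scores >= max(band_scores, na.rm = TRUE) - 1e-12)
    chosen <- bands[min(best)]          # ties -> lower-frequency band
    tr_fl <- unlist(blocks[[chosen]]$FL[-f])
    tr_mw <- unlist(blocks[[chosen]]$MW[-f])
    te_fl <- blocks[[chosen]]$FL[[f]]
    te_mw <- blocks[[chosen]]$MW[[f]]
    res <- cv_auc(tr_fl, tr_mw, te_fl, te_mw, n_obs, windows_per_fold,
                  fold_seed)
    if (is.na(res$auc)) {
      warning(sprintf("fold %d skipped: insufficient data", f))
      next
    }
    # threshold from training windows (MW is the positive class)
    tr_s_fl <- score_windows(tr_fl, windows_per_fold * (k - 1L),
                             res$models$fl, res$models$mw)
    tr_s_mw <- score_windows(tr_mw, windows_per_fold * (k - 1L),
                             res$models$fl, res$models$mw)
    thr <- youden_threshold(1 - c(tr_s_fl, tr_s_mw),
                            c(rep(FALSE, length(tr_s_fl)),
                              rep(TRUE, length(tr_s_mw))))
    te_s_fl <- score_windows(te_fl, windows_per_fold, res$models$fl,
                             res$models$mw)
    te_s_mw <- score_windows(te_mw, windows_per_fold, res$models$fl,
                             res$models$mw)
    pred_mw <- (1 - c(te_s_fl, te_s_mw)) >= thr
    lab_mw <- c(rep(FALSE, length(te_s_fl)), rep(TRUE, length(te_s_mw)))
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      fold = f, band = chosen, auc = res$auc,
      f1 = f1_score(pred_mw, lab_mw), stringsAsFactors = FALSE)
  }
  if (length(fold_rows) == 0L) stop("all folds skipped")
  folds <- do.call(rbind, fold_rows)
  structure(
    list(participant_id = participant_id, folds = folds,
         summary = c(auc_mean = mean(folds$auc), auc_sd = stats::sd(folds$auc),
                     f1_mean = mean(folds$f1), f1_sd = stats::sd(folds$f1))),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %s: AUC %.3f +/- %.3f, F1 %.3f +/- %.3f (%d folds)\n",
    x$participant_id, x$summary["auc_mean"], x$summary["auc_sd"],
    x$summary["f1_mean"], x$summary["f1_sd"], nrow(x$folds)))
  invisible(x)
}
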