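test_that("training traces are monotone and degenerate inputs are rejected", {
  set.seed(1)
  obs <- sample(4, 500, replace = TRUE)
  m <- fit_hmm(obs, n_obs = 4, seed = 1)
  expect_true(all(diff(m$train_log_likelihood_trace) > -1e-8))
  expect_equal(rowSums(m$A), rep(1, 2), tolerance = 1e-9)
  expect_equal(rowSums(m$B), rep(1, 2), tolerance = 1e-9)
  expect_equal(sum(m$pi), 1, tolerance = 1e-9)

  expect_error(fit_hmm(1:5), "at least 10")
  expect_error(fit_hmm(c(obs, 9), n_obs = 4), "outside the alphabet")
})

test_that("exactly uniform initialization is a symmetric fixed point", {
  set.seed(2)
  obs <- sample(4, 200, replace = TRUE)
  m <- fit_hmm(obs, n_obs = 4, seed = 1, perturb = 0, n_restarts = 1)
  expect_equal(m$A[1, ], m$A[2, ], tolerance = 1e-9)
  expect_equal(m$B[1, ], m$B[2, ], tolerance = 1e-9)
})

test_that("forward likelihood matches closed forms and exhaustive enumeration", {
  uni <- structure(
    list(n_hidden = 2, n_obs = 4,
         A = matrix(c(.7, .3, .4, .6), 2, 2, byrow = TRUE),
         B = matrix(0.25, 2, 4), pi = c(.5, .5), condition = NA,
         train_log_likelihood_trace = numeric(0)),
    class = "hmm_model")
  expect_equal(forward_likelihood(uni, c(1, 3, 2)), 3 * log(0.25),
               tolerance = 1e-12)

  for (s in 1:50) {
    set.seed(s)
    A <- matrix(runif(4), 2, 2)
    A <- A / rowSums(A)
    B <- matrix(runif(8), 2, 4)
    B <- B / rowSums(B)
    pi <- runif(2)
    pi <- pi / sum(pi)
    model <- structure(list(n_hidden = 2, n_obs = 4, A = A, B = B, pi = pi,
                            condition = NA,
                            train_log_likelihood_trace = numeric(0)),
                       class = "hmm_model")
    len <- sample(2:8, 1)
    obs <- sample(4, len, replace = TRUE)
    expect_equal(forward_likelihood(model, obs),
                 oracle_forward(A, B, pi, obs), tolerance = 1e-10)
    # appending a symbol cannot raise the sequence probability
    expect_lte(forward_likelihood(model, c(obs, sample(4, 1))),
               forward_likelihood(model, obs) + 1e-12)
  }
  expect_error(forward_likelihood(uni, integer(0)), "empty")
})

test_that("emission matrices are recovered from long sequences", {
  A <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  B <- matrix(c(.7, .1, .1, .1, .1, .1, .1, .7), 2, 4, byrow = TRUE)
  recovered <- 0
  for (s in 1:10) {
    obs <- gen_hmm(A, B, 2000, seed = s)
    m <- fit_hmm(obs, n_obs = 4, seed = s)
    err <- min(max(abs(m$B - B)), max(abs(m$B[2:1, ] - B)))
    recovered <- recovered + (err < 0.1)
    expect_true(all(diff(m$train_log_likelihood_trace) > -1e-8))
  }
  expect_gte(recovered, 6)
})

test_that("posterior scores obey the two-model identities", {
  mk <- function(p1) {
    structure(list(n_hidden = 1, n_obs = 2,
                   A = matrix(1, 1, 1), B = matrix(c(p1, 1 - p1), 1, 2),
                   pi = 1, condition = NA,
                   train_log_likelihood_trace = numeric(0)),
              class = "hmm_model")
  }
  m_fl <- mk(0.02)
  m_mw <- mk(0.01)
  expect_equal(score_fl(1L, m_fl, m_mw), 2 / 3, tolerance = 1e-12)
  expect_equal(score_fl(1L, m_fl, m_fl), 0.5)
  # complementarity
  s1 <- score_fl(c(1, 2, 1), m_fl, m_mw)
  s2 <- score_fl(c(1, 2, 1), m_mw, m_fl)
  expect_equal(s1 + s2, 1, tolerance = 1e-12)
})

test_that("rank AUC matches the pairwise oracle and external computation", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  for (s in 1:20) {
    set.seed(s)
    scores <- sample(10, 12, replace = TRUE)   # force ties
    labels <- sample(c(0, 1), 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
  expect_warning(res <- roc_auc(1:3, c(1, 1, 1)), "both classes")
  expect_true(is.na(res))
})

test_that("cross-validation separates distinct Markov dynamics and not identical ones", {
  bench <- benchmark_conditions()
  gen_chain <- function(P, n, seed) {
    set.seed(seed)
    s <- integer(n)
    s[1] <- sample(4, 1)
    for (i in 2:n) s[i] <- sample(4, 1, prob = P[s[i - 1], ])
    s
  }
  P_fl <- bench$fl_spec$state_transition_matrix
  P_mw <- bench$mw_spec$state_transition_matrix
  seqs <- list(alpha = list(
    FL = list(gen_chain(P_fl, 120, 1), gen_chain(P_fl, 120, 2)),
    MW = list(gen_chain(P_mw, 120, 3), gen_chain(P_mw, 120, 4))))
  res <- crossvalidate_participant(seqs, seed = 1)
  expect_gt(res$summary["auc_mean"], 0.8)

  res_again <- crossvalidate_participant(seqs, seed = 1)
  expect_identical(res$folds, res_again$folds)

  # identical generators: no information, AUC near chance over seeds
  aucs <- sapply(1:20, function(s) {
    seqs0 <- list(alpha = list(
      FL = list(gen_chain(P_fl, 120, 100 + s), gen_chain(P_fl, 120, 200 + s)),
      MW = list(gen_chain(P_fl, 120, 300 + s), gen_chain(P_fl, 120, 400 + s))))
    suppressWarnings(
      crossvalidate_participant(seqs0, seed = s)$summary["auc_mean"])
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("band selection prefers the informative band", {
  bench <- benchmark_conditions()
  gen_chain <- function(P, n, seed) {
    set.seed(seed)
    s <- integer(n)
    s[1] <- sample(4, 1)
    for (i in 2:n) s[i] <- sample(4, 1, prob = P[s[i - 1], ])
    s
  }
  P_fl <- bench$fl_spec$state_transition_matrix
  P_mw <- bench$mw_spec$state_transition_matrix
  noise <- function(seed) gen_chain(matrix(0.25, 4, 4), 120, seed)
  seqs <- list(
    delta = list(FL = list(noise(1), noise(2)),
                 MW = list(noise(3), noise(4))),
    alpha = list(FL = list(gen_chain(P_fl, 120, 5), gen_chain(P_fl, 120, 6)),
                 MW = list(gen_chain(P_mw, 120, 7), gen_chain(P_mw, 120, 8))))
  res <- crossvalidate_participant(seqs, seed = 2)
  expect_gt(mean(res$folds$band == "alpha"), 0.5)
})
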