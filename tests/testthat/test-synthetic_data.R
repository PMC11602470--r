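test_that("state libraries are mutually distinct and deterministic", {
  lib <- make_state_library(4, 8, seed = 1)
  expect_length(lib, 4)
  keys <- lapply(lib, mwnetdyn:::state_edge_set)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lt(mwnetdyn:::jaccard(keys[[i]], keys[[j]]), 0.5)
    }
  }
  lib2 <- make_state_library(4, 8, seed = 1)
  expect_identical(lib, lib2)

  tiny <- make_state_library(2, 3, seed = 1)
  expect_false(identical(mwnetdyn:::state_edge_set(tiny[[1]]),
                         mwnetdyn:::state_edge_set(tiny[[2]])))
  expect_error(make_state_library(1, 8, seed = 1), "at least 2")
  expect_error(planted_state("X", rbind(c(2, 2)), rbind(c(1, 3))),
               "self-pair")
  expect_error(planted_state("X", rbind(c(1, 2)), rbind(c(1, 3)),
                             phase_lag = 0), "phase_lag")
})

test_that("simulated trials are reproducible and internally consistent", {
  lib <- make_state_library(4, 8, seed = 2)
  bench <- benchmark_conditions(seed = 2)
  a <- simulate_trial(lib, bench$fl_spec, 20, "alpha", seed = 9)
  b <- simulate_trial(lib, bench$fl_spec, 20, "alpha", seed = 9)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth, b$truth)

  # state path and change points agree
  expect_equal(a$change_points, a$truth$onset[-1])
  expect_equal(a$truth$offset[-nrow(a$truth)], a$truth$onset[-1])
  expect_equal(max(a$truth$offset), 20)

  expect_error(simulate_trial(lib, bench$fl_spec, 5, "alpha", seed = 1),
               "at least 10")
  expect_warning(simulate_trial(lib, condition_spec(
    "FL", bench$fl_spec$state_transition_matrix, dwell_mean = 8), 12,
    "alpha", seed = 1), "too few switches")
})

test_that("generated signals are band-limited", {
  lib <- make_state_library(4, 8, seed = 3)
  bench <- benchmark_conditions(seed = 3)
  tr <- simulate_trial(lib, bench$fl_spec, 30, "alpha", seed = 4)
  x <- tr$recording$data[1, ]
  p <- Mod(fft(x))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) / n * 256
  half <- freqs <= 128
  in_band <- half & freqs >= 8 & freqs <= 13
  expect_gt(sum(p[in_band]) / sum(p[half]), 0.9)
})

test_that("the planted phase lag is recoverable from coupled channels", {
  pair <- planted_state("A", matrix(integer(0), 0, 2), rbind(c(1, 2)),
                        amp_strength = 0.9, phase_lag = pi / 4)
  lib <- list(pair)
  attr(lib, "n_channels") <- 3L
  spec <- condition_spec("FL", matrix(1, 1, 1), dwell_mean = 5, snr = 4)
  tr <- simulate_trial(lib, spec, 60, "alpha", seed = 5,
                       path = data.frame(onset = 0, offset = 60, state = 1))
  z <- analytic_signal(tr$recording$data[1:2, ])
  dphi <- Arg(z[1, ] * Conj(z[2, ]))
  circ_mean <- Arg(mean(exp(1i * dphi)))
  expect_lt(abs(circ_mean - pi / 4), 0.2)
})

test_that("planted amplitude coupling separates from background connectivity", {
  lib <- make_state_library(2, 8, seed = 6)
  spec <- condition_spec("FL", matrix(c(0, 1, 1, 0), 2, 2), dwell_mean = 5,
                         snr = 2)
  hits <- 0
  for (s in 1:5) {
    tr <- simulate_trial(lib, spec, 60, "alpha", seed = s,
                         path = data.frame(onset = 0, offset = 60, state = 1))
    m <- aec(tr$recording$data)
    e <- lib[[1]]$amp_edges
    planted <- m[e[1, 1], e[1, 2]]
    keys <- mwnetdyn:::edge_key(e)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    bg <- m[upper.tri(m)][!mwnetdyn:::edge_key(ut) %in%
                            mwnetdyn:::state_edge_set(lib[[1]])]
    hits <- hits + (planted > quantile(bg, 0.95))
  }
  expect_gte(hits, 4)
})

test_that("uncoupled simulations are indistinguishable from independent noise", {
  flat <- planted_state("A", rbind(c(1, 2)), matrix(integer(0), 0, 2),
                        amp_strength = 0)
  lib <- list(flat)
  attr(lib, "n_channels") <- 4L
  spec <- condition_spec("FL", matrix(1, 1, 1), dwell_mean = 5)
  planted_vals <- indep_vals <- numeric(0)
  for (s in 1:25) {
    tr <- simulate_trial(lib, spec, 10, "alpha", seed = s,
                         path = data.frame(onset = 0, offset = 10, state = 1))
    planted_vals <- c(planted_vals, aec(tr$recording$data)[1, 2])
    set.seed(s + 500)
    ref <- matrix(rnorm(4 * 2560), nrow = 4)
    taps <- mwnetdyn:::fir_bandpass_taps(8, 13, 256)
    ref <- t(apply(ref, 1, function(ch) mwnetdyn:::filtfilt_fir(taps, ch)))
    indep_vals <- c(indep_vals, aec(ref)[1, 2])
  }
  expect_gt(wilcox.test(planted_vals, indep_vals)$p.value, 0.01)
})

test_that("participants get labeled trials with derived seeds", {
  bench <- benchmark_conditions(seed = 8)
  trials <- simulate_participant(bench$library, bench$fl_spec,
                                 bench$mw_spec, 2, 15, "alpha", seed = 3)
  expect_named(trials, c("FL-1", "FL-2", "MW-1", "MW-2"))
  expect_equal(trials[["MW-2"]]$recording$trial_label, "MW-2")
  again <- simulate_participant(bench$library, bench$fl_spec,
                                bench$mw_spec, 2, 15, "alpha", seed = 3)
  expect_identical(trials[["FL-1"]]$recording$data,
                   again[["FL-1"]]$recording$data)
  expect_false(identical(trials[["FL-1"]]$recording$data,
                         trials[["FL-2"]]$recording$data))
})
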