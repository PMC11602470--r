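test_that("segment runs consolidate and break across gaps", {
  s <- build_state_sequence(c("A", "A", "B"), c(0, 2, 3), c(2, 3, 4))
  expect_equal(s$runs$state, c("A", "B"))
  expect_equal(s$runs$duration, c(3, 1))
  expect_equal(s$total_duration, 4)

  single <- build_state_sequence("A", 0, 2)
  expect_equal(nrow(single$runs), 1)

  gap <- build_state_sequence(c("A", "A"), c(0, 3), c(2, 5))
  expect_equal(gap$runs$state, c("A", "A"))
  expect_equal(nrow(mwnetdyn:::transition_pairs(gap)), 0)

  expect_error(build_state_sequence(c("A", "B"), c(0, 1), c(2, 3)),
               "overlapping")
})

test_that("per-state metrics follow their definitions", {
  s <- build_state_sequence(c("A", "B", "A", "C"), c(0, 2, 3, 4),
                            c(2, 3, 4, 5))
  m <- sequence_metrics(s)
  a <- m[m$state == "A", ]
  expect_equal(a$frequency, 0.4)
  expect_equal(a$mean_duration, 1.5)
  expect_equal(a$coverage, 0.6)
  expect_equal(sum(m$coverage), 1)

  one <- sequence_metrics(build_state_sequence("A", 0, 4),
                          all_states = c("A", "B"))
  expect_equal(one$frequency[one$state == "A"], 0.25)
  expect_equal(one$coverage[one$state == "A"], 1)
  expect_equal(one$frequency[one$state == "B"], 0)
  expect_true(is.na(one$mean_duration[one$state == "B"]))
})

test_that("observed transition probabilities normalize over ordered pairs", {
  s <- run_sequence(c("A", "B", "A", "C"))
  o <- observed_transitions(s)
  expect_equal(o["A", "B"], 1 / 3)
  expect_equal(o["B", "A"], 1 / 3)
  expect_equal(o["A", "C"], 1 / 3)
  expect_equal(sum(o), 1)
  expect_true(all(diag(o) == 0))

  two <- observed_transitions(run_sequence(c("A", "B")))
  expect_equal(two["A", "B"], 1)
  expect_warning(res <- observed_transitions(build_state_sequence("A", 0, 1)),
                 "no transitions")
  expect_true(all(is.na(res)))
})

test_that("frequency-expected transitions satisfy the closed-form identities", {
  # occurrence probabilities 0.5 / 0.25 / 0.25
  s <- run_sequence(c("A", "B", "A", "C"))
  e <- expected_transitions(s)
  expect_equal(e["A", "B"], 0.25 * 0.5 / 0.5)
  expect_equal(e["B", "A"], 0.5 * 0.25 / 0.75)

  # uniform four states: every cell (1/16) / (3/4) = 1/12
  u <- run_sequence(rep(c("A", "B", "C", "D"), 6))
  eu <- expected_transitions(u)
  off <- eu[row(eu) != col(eu)]
  expect_true(all(abs(off - 1 / 12) < 1e-12))

  # row identity and conservation
  for (seed in 1:5) {
    sq <- run_sequence(gen_memoryless(60, c(.4, .3, .2, .1), seed))
    em <- expected_transitions(sq)
    p <- sapply(rownames(em), function(x) mean(sq$runs$state == x))
    expect_equal(unname(rowSums(em)), unname(p), tolerance = 1e-12)
    expect_equal(sum(em), 1, tolerance = 1e-12)
  }

  expect_warning(bad <- expected_transitions(build_state_sequence("A", 0, 1)),
                 "single-state")
  expect_true(all(is.na(bad)))
})

test_that("the chi-square distance matches a scalar-loop oracle", {
  o <- matrix(c(0, .3, .2, 0, 0, .1, .25, .15, 0), 3, 3)
  e <- matrix(c(0, .25, .25, .05, 0, .1, .2, .15, 0), 3, 3)
  expect_equal(chi_square_distance(o, o), 0)
  expect_equal(chi_square_distance(o, e), oracle_chi2(o, e),
               tolerance = 1e-12)

  # single differing off-diagonal cell
  e2 <- o
  e2[1, 2] <- 0.2
  o2 <- o
  o2[1, 2] <- 0.3
  expect_equal(chi_square_distance(o2, e2), 0.1^2 / 0.2, tolerance = 1e-12)

  e3 <- o
  e3[2, 1] <- 0
  expect_error(chi_square_distance(o, e3), "expected probability 0")
})

test_that("the randomness test rejects structured chains and accepts itself", {
  cyc <- run_sequence(gen_cycle(100, 1))
  ts <- transition_randomness_test(cyc, n_perm = 999, seed = 1)
  expect_lte(ts$p_value, 0.05)
  expect_gte(ts$chi_square_d, 0)
  expect_equal(ts$n_permutations, 999)

  # perfectly frequency-consistent data should not look structured
  nul <- run_sequence(gen_memoryless(200, rep(0.25, 4), 2))
  ts2 <- transition_randomness_test(nul, n_perm = 499, seed = 2)
  expect_gt(ts2$p_value, 0.01)

  expect_error(transition_randomness_test(cyc, n_perm = 10), "at least 100")
})

test_that("the randomness test pools a condition's trials", {
  seqs <- lapply(1:4, function(s) run_sequence(gen_cycle(60, s)))
  ts <- transition_randomness_test(seqs, n_perm = 499, seed = 3)
  expect_lte(ts$p_value, 0.05)
  expect_equal(sum(ts$observed), 1, tolerance = 1e-9)
  expect_equal(sum(ts$expected), 1, tolerance = 1e-2)
})
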