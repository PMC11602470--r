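# Independent brute-force oracles. These deliberately use naive scalar
# computations (loops, exhaustive enumeration) and never call the package
# functions they check.

# All-pairs shortest distances by exhaustive enumeration of simple paths
# (feasible for <= 5 nodes). Edge distance = 1 / weight, absent if weight 0.
oracle_distances <- function(w) {
  n <- nrow(w)
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      best <- Inf
      inner <- setdiff(seq_len(n), c(i, j))
      for (sz in 0:length(inner)) {
        combos <- if (sz == 0) list(integer(0)) else
          utils::combn(inner, sz, simplify = FALSE)
        for (cmb in combos) {
          for (mid in perms_of(cmb)) {
            nodes <- c(i, mid, j)
            len <- 0
            ok <- TRUE
            for (k in seq_len(length(nodes) - 1L)) {
              wt <- w[nodes[k], nodes[k + 1L]]
              if (wt <= 0) { ok <- FALSE; break }
              len <- len + 1 / wt
            }
            if (ok && len < best) best <- len
          }
        }
      }
      dmat[i, j] <- best
    }
  }
  dmat
}

oracle_closeness <- function(w) {
  d <- oracle_distances(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    di <- d[i, -i]
    if (any(!is.finite(di))) 0 else 1 / mean(di)
  })
}

# log P(obs | model) by exhaustive summation over hidden paths
oracle_forward <- function(A, B, pi, obs) {
  n <- nrow(A)
  T_len <- length(obs)
  paths <- expand.grid(rep(list(seq_len(n)), T_len))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    h <- as.integer(paths[r, ])
    p <- pi[h[1]] * B[h[1], obs[1]]
    if (T_len > 1) {
      for (t in 2:T_len) p <- p * A[h[t - 1], h[t]] * B[h[t], obs[t]]
    }
    total <- total + p
  }
  log(total)
}

# Pearson correlation by the explicit scalar formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Spearman = Pearson on midranks
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# chi-square distance, scalar loop over off-diagonal cells
oracle_chi2 <- function(o, e) {
  s <- 0
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      if (i == j) next
      if (e[i, j] == 0 && o[i, j] == 0) next
      s <- s + (o[i, j] - e[i, j])^2 / e[i, j]
    }
  }
  s
}

# Euclidean distance between layer-averaged centrality profiles
oracle_edmcc <- function(v1, v2) {
  m1 <- v1$values; m2 <- v2$values
  s <- 0
  for (i in seq_len(nrow(m1))) {
    a <- 0; b <- 0
    for (l in seq_len(ncol(m1))) {
      a <- a + m1[i, l] / ncol(m1)
      b <- b + m2[i, l] / ncol(m2)
    }
    s <- s + (a - b)^2
  }
  sqrt(s)
}

# AUC by exhaustive pairwise comparison
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# Hilbert amplitude envelope / phase of one channel via a naive O(n^2) DFT
oracle_analytic <- function(x) {
  n <- length(x)
  X <- complex(n)
  for (k in 0:(n - 1)) {
    X[k + 1] <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- X * h
  z <- complex(n)
  for (t in 0:(n - 1)) {
    z[t + 1] <- sum(X * exp(2i * pi * (0:(n - 1)) * t / n)) / n
  }
  z
}

# --- generators used across tests ------------------------------------------

# consolidated run sequence with unit durations
run_sequence <- function(states, band = "alpha") {
  build_state_sequence(states, seq_along(states) - 1, seq_along(states),
                       band = band)
}

# memoryless no-self-repeat chain matched to the frequency expectation
gen_memoryless <- function(n, p, seed) {
  set.seed(seed)
  k <- length(p)
  s <- integer(n)
  s[1] <- sample(k, 1, prob = p)
  for (i in 2:n) {
    q <- p
    q[s[i - 1]] <- 0
    s[i] <- sample(k, 1, prob = q / sum(q))
  }
  LETTERS[s]
}

# noisy 4-state cycle (strong first-order structure)
gen_cycle <- function(n, seed, eps = 0.1) {
  set.seed(seed)
  k <- 4
  s <- integer(n)
  s[1] <- sample(k, 1)
  for (i in 2:n) {
    nxt <- s[i - 1] %% k + 1
    q <- rep(eps / 2, k)
    q[s[i - 1]] <- 0
    q[nxt] <- 1 - eps
    s[i] <- sample(k, 1, prob = q / sum(q))
  }
  LETTERS[s]
}

# centrality-like planted profiles: elevated channel groups
planted_profiles <- function(seed) {
  groups <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 3, 5, 7), c(2, 4, 6, 8))
  set.seed(seed)
  profiles <- t(sapply(groups, function(g) {
    p <- rep(0.3, 8)
    p[g] <- 0.7
    p
  }))
  profiles + matrix(runif(32, -0.05, 0.05), 4, 8)
}

# 2-state hidden Markov sampler for recovery tests
gen_hmm <- function(A, B, n, seed) {
  set.seed(seed)
  h <- 1L
  obs <- integer(n)
  for (t in seq_len(n)) {
    h <- sample(nrow(A), 1, prob = A[h, ])
    obs[t] <- sample(ncol(B), 1, prob = B[h, ])
  }
  obs
}

# random normalized two-layer multiplex over n nodes
random_multiplex <- function(n, seed) {
  set.seed(seed)
  mk <- function() {
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    normalize_layer(w)
  }
  new_multiplex(list(AEC = mk(), IPLV = mk()), normalized = TRUE)
}
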