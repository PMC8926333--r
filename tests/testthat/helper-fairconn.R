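# Shared fixtures and independent oracles for the test suite.

# Small default cohort used across tests.
tiny_config <- function(seed = 1, ...) {
  synth_config(n_majority = 60, n_minority = 20, n_roi = 10, seed = seed, ...)
}

# Exhaustive-search oracle for the rectangular assignment problem.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    }
  }
  best
}

# Brute-force Benjamini-Hochberg: scan all step-up thresholds directly.
brute_force_bh <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(n)) {
    if (p[ord[i]] <= q * i / n) k <- i
  }
  rej <- logical(n)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Direct Pearson + Fisher z over uncensored frames, one edge at a time.
oracle_fisher_z <- function(signal, keep = rep(TRUE, nrow(signal))) {
  sub <- signal[keep, , drop = FALSE]
  p <- ncol(sub)
  z <- matrix(0, p, p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      r <- cor(sub[, a], sub[, b])
      r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
      z[a, b] <- z[b, a] <- atanh(r)
    }
  }
  z
}

# A random symmetric matrix with zero diagonal.
random_symmetric <- function(p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * p), p, p)
  m <- m + t(m)
  diag(m) <- 0
  m
}
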