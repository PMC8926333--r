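# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package flows through
# this so that a single integer seed makes every stage reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a fixed family of sub-seeds from one master seed. Offsets are fixed
# constants so each stage reads an independent, reproducible stream.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483629L
}

# Population-denominator (1/N) variance and covariance, matching the printed
# definitions of SST / SSE and of the association covariances.
pop_var <- function(x) mean((x - mean(x))^2)

pop_cov_vec <- function(X, y) {
  # covariance of each column of X with y, 1/N denominator
  n <- length(y)
  xc <- sweep(X, 2L, colMeans(X))
  as.numeric(crossprod(xc, y - mean(y))) / n
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g.", name, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}
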