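#' Configure the synthetic multi-group connectome dataset generator
#'
#' Builds a validated configuration for [generate_dataset()]. The generator
#' emulates the statistical structure that the downstream audit assumes:
#' vectorized Fisher-z functional connectivity (FC) drawn from a latent
#' covariance shared across groups, behavioral scores produced by
#' group-specific linear edge-weight patterns plus noise, confounds that load
#' on both FC and behavior, and site/family grouping structure.
#'
#' The two ground-truth edge-weight patterns (`w_majority`, `w_minority`) are
#' constructed here, deterministically from `seed`: both are unit-norm,
#' mean-zero vectors over the `n_roi * (n_roi - 1) / 2` edges whose Pearson
#' correlation equals `pattern_similarity` exactly. Group differences in the
#' generative model live only in the weight pattern, the behavioral mean
#' shift, the behavioral variance ratio, and (optionally) confound loadings;
#' the latent FC covariance itself is shared, so distribution shift between
#' groups is controlled, not incidental.
#'
#' The latent FC model is low-rank plus diagonal: an edge vector is
#' `mu + A z + sqrt(d) * eps + Gamma x`, with `A` of rank `latent_rank`
#' carrying a `latent_share` fraction of the edge variance, a diagonal part
#' carrying the rest, and `Gamma` the (optional) confound-to-edge loading
#' matrix. Total edge variance is normalized so the average edge standard
#' deviation equals `edge_sd` (Fisher-z units).
#'
#' When `noise_sd > 0`, minority behavioral noise is rescaled so that the
#' population variance of the minority score is exactly
#' `group_variance_ratio` times the majority variance; when `noise_sd = 0`
#' both groups are noiseless and no rescaling is applied.
#'
#' @param n_majority,n_minority,n_other Group sizes. `n_other` subjects follow
#'   the majority weight pattern but are excluded from matched comparisons.
#' @param n_roi Number of regions of interest; FC vectors have
#'   `n_roi * (n_roi - 1) / 2` edges.
#' @param n_sites Number of acquisition sites.
#' @param family_size_distribution Named numeric vector of probabilities over
#'   family sizes, e.g. `c("1" = .6, "2" = .3, "3" = .1)`. Families never
#'   straddle sites.
#' @param pattern_similarity Pearson correlation in `[-1, 1]` between the
#'   majority and minority edge-weight patterns.
#' @param noise_sd Standard deviation of the majority behavioral noise
#'   (score units); `>= 0`.
#' @param group_mean_shift Additive offset of the minority behavioral mean.
#' @param group_variance_ratio Minority / majority population variance ratio
#'   of the behavioral score; `> 0`.
#' @param confound_loadings List with elements `y` (named numeric: loading of
#'   each confound on the behavioral score) and `fc` (named numeric: loading
#'   scale of each confound on a random subset of `fc_n_edges` edges).
#'   Confounds are `age` (standard normal), `motion` (standard normal) and
#'   `gender` (Bernoulli 1/2). Defaults to all-zero loadings.
#' @param fc_n_edges Number of edges each confound loads on when its `fc`
#'   loading is nonzero.
#' @param frames_per_run,runs_per_subject Dimensions of the optional ROI time
#'   series emitted by [generate_timeseries()].
#' @param motion_params List with `spike_rate` (per-frame probability of a
#'   motion spike), `fd_spike` (FD value at a spike, mm; baseline FD is 0)
#'   and `spike_scale` (multiplicative signal inflation at a spike, which
#'   drives DVARS).
#' @param edge_sd Average edge standard deviation in Fisher-z units.
#' @param latent_rank Rank of the shared low-rank FC component.
#' @param latent_share Fraction of the edge variance carried by the shared
#'   low-rank component (the rest is diagonal). Only the low-rank part of a
#'   weight pattern is learnable when subjects are fewer than edges, so this
#'   bounds the achievable out-of-sample accuracy.
#' @param seed Integer master seed; all sub-streams derive from it by fixed
#'   offsets.
#'
#' @return An object of class `synth_config`: a validated list additionally
#'   holding the constructed weight vectors and latent structure.
#' @seealso [generate_dataset()], [ground_truth_association()],
#'   [noise_sd_for_r2()]
#' @export
#' @examples
#' cfg <- synth_config(n_majority = 60, n_minority = 20, n_roi = 12, seed = 1)
#' cor(cfg$w_majority, cfg$w_minority)  # equals pattern_similarity
synth_config <- function(n_majority = 400,
                         n_minority = 100,
                         n_other = 0,
                         n_roi = 40,
                         n_sites = 1,
                         family_size_distribution = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                         pattern_similarity = 1,
                         noise_sd = NULL,
                         group_mean_shift = 0,
                         group_variance_ratio = 1,
                         confound_loadings = NULL,
                         fc_n_edges = 50,
                         frames_per_run = 200,
                         runs_per_subject = 2,
                         motion_params = list(spike_rate = 0.05, fd_spike = 0.8,
                                              spike_scale = 6),
                         edge_sd = 0.15,
                         latent_rank = 10,
                         latent_share = 0.5,
                         seed = 1) {
  n_majority <- assert_count(n_majority, "n_majority")
  n_minority <- assert_count(n_minority, "n_minority")
  n_other <- assert_count(n_other, "n_other", min = 0)
  n_roi <- assert_count(n_roi, "n_roi", min = 3)
  n_sites <- assert_count(n_sites, "n_sites")
  assert_scalar_number(pattern_similarity, "pattern_similarity", -1, 1)
  assert_scalar_number(group_mean_shift, "group_mean_shift")
  assert_scalar_number(group_variance_ratio, "group_variance_ratio", 0,
                       strict_lower = TRUE)
  assert_scalar_number(edge_sd, "edge_sd", 0, strict_lower = TRUE)
  latent_rank <- assert_count(latent_rank, "latent_rank")
  assert_scalar_number(latent_share, "latent_share", 0, 1)
  frames_per_run <- assert_count(frames_per_run, "frames_per_run", min = 10)
  runs_per_subject <- assert_count(runs_per_subject, "runs_per_subject")
  seed <- assert_count(seed, "seed", min = 0)

  if (is.null(names(family_size_distribution)) ||
      any(is.na(as.integer(names(family_size_distribution)))) ||
      any(family_size_distribution < 0) ||
      sum(family_size_distribution) <= 0) {
    abort("`family_size_distribution` must be named probabilities over positive integer sizes.")
  }
  family_size_distribution <- family_size_distribution / sum(family_size_distribution)

  confound_names <- c("age", "motion", "gender")
  if (is.null(confound_loadings)) {
    confound_loadings <- list(
      y = setNames(numeric(3), confound_names),
      fc = setNames(numeric(3), confound_names)
    )
  }
  if (!all(c("y", "fc") %in% names(confound_loadings))) {
    abort("`confound_loadings` must have elements `y` and `fc`.")
  }
  for (slot in c("y", "fc")) {
    v <- confound_loadings[[slot]]
    if (!all(confound_names %in% names(v))) {
      abort(sprintf("`confound_loadings$%s` must be named for %s.",
                    slot, paste(confound_names, collapse = ", ")))
    }
    confound_loadings[[slot]] <- v[confound_names]
  }

  n_edges <- n_roi * (n_roi - 1L) / 2L
  sub <- derive_seeds(seed, 4)

  # Weight pair: unit-norm, mean-zero, Pearson correlation == pattern_similarity.
  w <- with_seed(sub[1], make_weight_pair(n_edges, pattern_similarity))

  # Shared latent covariance: `latent_share` of the (normalized) edge
  # variance is low-rank, the rest diagonal; mean edge variance == edge_sd^2.
  latent <- with_seed(sub[2], {
    A <- matrix(rnorm(n_edges * latent_rank), n_edges, latent_rank)
    d <- runif(n_edges, 0.5, 1.5)
    share <- min(max(latent_share, 1e-8), 1 - 1e-8)
    A <- A * sqrt(mean(d) * share / ((1 - share) * mean(rowSums(A^2))))
    tot <- mean(rowSums(A^2) + d)
    scl <- edge_sd^2 / tot
    list(A = A * sqrt(scl), d = d * scl,
         mu = rnorm(n_edges, mean = 0.15, sd = 0.05))
  })

  # Confound-to-edge loadings on random edge subsets.
  fc_n_edges <- assert_count(fc_n_edges, "fc_n_edges", min = 0)
  latent$Gamma <- with_seed(sub[3], {
    G <- matrix(0, n_edges, 3, dimnames = list(NULL, confound_names))
    for (j in seq_len(3)) {
      amp <- confound_loadings$fc[[j]]
      if (amp != 0) {
        idx <- sample.int(n_edges, min(fc_n_edges, n_edges))
        G[idx, j] <- rnorm(length(idx), sd = amp)
      }
    }
    G
  })

  if (is.null(noise_sd)) {
    noise_sd <- sqrt(drop(crossprod(w$majority, sigma_times(latent, w$majority))))
  }
  assert_scalar_number(noise_sd, "noise_sd", 0)

  cfg <- structure(list(
    n_majority = n_majority, n_minority = n_minority, n_other = n_other,
    n_roi = n_roi, n_edges = n_edges, n_sites = n_sites,
    family_size_distribution = family_size_distribution,
    pattern_similarity = pattern_similarity,
    w_majority = w$majority, w_minority = w$minority,
    noise_sd = noise_sd, group_mean_shift = group_mean_shift,
    group_variance_ratio = group_variance_ratio,
    confound_loadings = confound_loadings, fc_n_edges = fc_n_edges,
    frames_per_run = frames_per_run, runs_per_subject = runs_per_subject,
    motion_params = motion_params,
    edge_sd = edge_sd, latent_rank = latent_rank,
    latent_share = latent_share, latent = latent, seed = seed
  ), class = "synth_config")

  stopifnot(abs(cor(cfg$w_majority, cfg$w_minority) - pattern_similarity) < 1e-6)
  cfg
}

# Two unit-norm mean-zero vectors with exact Pearson correlation rho.
make_weight_pair <- function(p, rho) {
  g1 <- rnorm(p)
  g2 <- rnorm(p)
  u <- g1 - mean(g1)
  u <- u / sqrt(sum(u^2))
  v <- g2 - mean(g2)
  v <- v - sum(u * v) * u
  v <- v / sqrt(sum(v^2))
  list(majority = u, minority = rho * u + sqrt(max(0, 1 - rho^2)) * v)
}

# Sigma_c %*% x without forming the edge-by-edge covariance:
# Sigma_c = A A' + diag(d) + Gamma V_x Gamma'.
sigma_times <- function(latent, x) {
  out <- latent$A %*% crossprod(latent$A, x) + latent$d * x
  if (!is.null(latent$Gamma)) {
    vx <- confound_variances()
    out <- out + latent$Gamma %*% (vx * crossprod(latent$Gamma, x))
  }
  drop(out)
}

confound_variances <- function() c(age = 1, motion = 1, gender = 0.25)

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  groups: %d majority, %d minority, %d other; %d site(s)\n",
              x$n_majority, x$n_minority, x$n_other, x$n_sites))
  cat(sprintf("  %d ROIs (%d edges); pattern similarity %.3f\n",
              x$n_roi, x$n_edges, x$pattern_similarity))
  cat(sprintf("  noise sd %.4f; mean shift %.3f; variance ratio %.3f; seed %d\n",
              x$noise_sd, x$group_mean_shift, x$group_variance_ratio, x$seed))
  invisible(x)
}

#' Noise level giving a target population R-squared
#'
#' Computes the behavioral noise standard deviation for which the majority
#' group's population squared correlation between the score and its FC signal
#' component equals `r2`, using the closed-form signal variance
#' `w' Sigma w` of the configured latent model.
#'
#' @param config A [synth_config()].
#' @param r2 Target population R-squared in `(0, 1)`.
#' @return A noise standard deviation.
#' @export
noise_sd_for_r2 <- function(config, r2) {
  stopifnot(inherits(config, "synth_config"))
  assert_scalar_number(r2, "r2", 0, 1)
  if (r2 <= 0 || r2 >= 1) abort("`r2` must be strictly between 0 and 1.")
  s <- drop(crossprod(config$w_majority, sigma_times(config$latent, config$w_majority)))
  sqrt(s * (1 - r2) / r2)
}
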