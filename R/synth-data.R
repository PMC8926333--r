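#' Generate a synthetic multi-group connectome dataset
#'
#' Draws a complete dataset under the generative model described in
#' [synth_config()]: per-subject vectorized Fisher-z FC from the shared
#' latent covariance, confounds (`age`, `motion`, `gender`), site and family
#' structure, and a behavioral score
#' `y = c' w_group + gamma' x + shift + noise`, where the mean shift applies
#' to the minority group only and per-group noise is scaled so the minority /
#' majority population variance ratio equals `group_variance_ratio` (unless
#' `noise_sd = 0`, in which case both groups are exactly noiseless).
#'
#' @param config A [synth_config()].
#' @return A tibble of class `synth_dataset` with one row per subject and
#'   columns `subject_id`, `group` (`"majority"`, `"minority"`, `"other"`),
#'   `site`, `family`, `age`, `motion`, `gender`, `y_signal` (the noiseless
#'   score), `y`, and a matrix column `fc` (subjects x edges, strictly
#'   lower-triangular column-major edge order). The configuration and the
#'   ground truth (weight vectors, per-group noise standard deviations) are
#'   attached as attributes `config` and `truth`.
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_majority = 40, n_minority = 10,
#'                                    n_roi = 10, seed = 7))
#' dplyr::count(d, group)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  str <- gen_structure(config)
  beh <- gen_behavior(config, str, config$w_majority, config$w_minority,
                      seed_offset = 4L)
  out <- str$subjects
  out$y_signal <- beh$y_signal
  out$y <- beh$y
  out$fc <- str$fc
  attr(out, "config") <- config
  attr(out, "truth") <- list(w_majority = config$w_majority,
                             w_minority = config$w_minority,
                             noise_sd = beh$noise_sd)
  class(out) <- c("synth_dataset", class(out))
  out
}

#' Generate a suite of behaviors over one shared FC dataset
#'
#' Emulates a multi-behavior study: the FC matrices, confounds and grouping
#' structure are generated once, and each behavior gets its own pair of
#' ground-truth weight patterns with its own majority/minority pattern
#' similarity. Useful for experiments that grade the divergence between group
#' association patterns across behaviors.
#'
#' Each behavior's noise is rescaled so its majority signal-to-noise ratio
#' equals the configured one: behaviors differ in their weight patterns, not
#' in how predictable they are.
#'
#' @param config A [synth_config()]; its `pattern_similarity` is ignored in
#'   favor of `pattern_similarities`.
#' @param pattern_similarities Numeric vector, one similarity per behavior.
#' @return A `synth_dataset` tibble with one score column per behavior
#'   (`y_1`, `y_2`, ...) plus `y_signal_1`, ... ; attribute `truth` is a list
#'   with one entry per behavior.
#' @export
generate_behavior_suite <- function(config, pattern_similarities) {
  stopifnot(inherits(config, "synth_config"),
            is.numeric(pattern_similarities), length(pattern_similarities) >= 1,
            all(abs(pattern_similarities) <= 1))
  str <- gen_structure(config)
  out <- str$subjects
  truth <- vector("list", length(pattern_similarities))
  wseeds <- derive_seeds(config$seed + 271L, length(pattern_similarities))
  s_ref <- drop(crossprod(config$w_majority,
                          sigma_times(config$latent, config$w_majority)))
  for (b in seq_along(pattern_similarities)) {
    w <- with_seed(wseeds[b],
                   make_weight_pair(config$n_edges, pattern_similarities[b]))
    s_b <- drop(crossprod(w$majority, sigma_times(config$latent, w$majority)))
    beh <- gen_behavior(config, str, w$majority, w$minority,
                        seed_offset = 4L + 3L * b,
                        noise_scale = sqrt(s_b / s_ref))
    out[[paste0("y_signal_", b)]] <- beh$y_signal
    out[[paste0("y_", b)]] <- beh$y
    truth[[b]] <- list(w_majority = w$majority, w_minority = w$minority,
                       pattern_similarity = pattern_similarities[b],
                       noise_sd = beh$noise_sd)
  }
  out$fc <- str$fc
  attr(out, "config") <- config
  attr(out, "truth") <- truth
  attr(out, "behaviors") <- paste0("y_", seq_along(pattern_similarities))
  class(out) <- c("synth_dataset", class(out))
  out
}

# Shared structure: groups, families, sites, confounds, FC matrix.
gen_structure <- function(config) {
  sub <- derive_seeds(config$seed, 12)
  n <- config$n_majority + config$n_minority + config$n_other
  group <- rep(c("majority", "minority", "other"),
               c(config$n_majority, config$n_minority, config$n_other))

  fam_site <- with_seed(sub[4], {
    sizes <- as.integer(names(config$family_size_distribution))
    fam <- integer(n)
    fid <- 0L
    for (g in unique(group)) {
      idx <- which(group == g)
      pos <- 1L
      while (pos <= length(idx)) {
        fid <- fid + 1L
        k <- sample(sizes, 1, prob = config$family_size_distribution)
        take <- idx[pos:min(pos + k - 1L, length(idx))]
        fam[take] <- fid
        pos <- pos + k
      }
    }
    site_of_family <- sample.int(config$n_sites, fid, replace = TRUE)
    list(family = fam, site = site_of_family[fam])
  })

  x <- with_seed(sub[5], cbind(age = rnorm(n), motion = rnorm(n),
                               gender = rbinom(n, 1, 0.5)))

  fc <- with_seed(sub[6], {
    lat <- config$latent
    Z <- matrix(rnorm(n * config$latent_rank), n, config$latent_rank)
    E <- matrix(rnorm(n * config$n_edges), n, config$n_edges)
    C <- tcrossprod(Z, lat$A) + E * rep(sqrt(lat$d), each = n)
    C <- sweep(C, 2L, lat$mu, "+")
    C + x %*% t(lat$Gamma)
  })

  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    site = sprintf("site%02d", fam_site$site),
    family = sprintf("F%04d", fam_site$family),
    age = x[, "age"], motion = x[, "motion"], gender = x[, "gender"]
  )
  list(subjects = subjects, fc = fc, x = x)
}

# Behavioral score for one weight pair, with exact population variance
# targeting of the minority group. `noise_scale` rescales the configured
# noise sd (used by behavior suites to hold signal-to-noise constant).
gen_behavior <- function(config, str, w_majority, w_minority, seed_offset,
                         noise_scale = 1) {
  n <- nrow(str$subjects)
  group <- str$subjects$group
  gamma <- config$confound_loadings$y
  lat <- config$latent
  vx <- confound_variances()

  w_of <- list(majority = w_majority, minority = w_minority, other = w_majority)
  signal <- numeric(n)
  for (g in names(w_of)) {
    idx <- which(group == g)
    if (length(idx)) signal[idx] <- drop(str$fc[idx, , drop = FALSE] %*% w_of[[g]])
  }
  conf_term <- drop(str$x %*% gamma)
  shift <- ifelse(group == "minority", config$group_mean_shift, 0)
  y_signal <- signal + conf_term + shift

  # Population variance of the deterministic part per group:
  # w' Sigma0 w + sum_j vx_j (Gamma' w + gamma)_j^2
  det_var <- function(w) {
    s0 <- drop(crossprod(w, lat$A %*% crossprod(lat$A, w) + lat$d * w))
    b <- drop(crossprod(lat$Gamma, w)) + gamma
    s0 + sum(vx * b^2)
  }
  v_det <- c(majority = det_var(w_majority), minority = det_var(w_minority),
             other = det_var(w_majority))

  sd_majority <- config$noise_sd * noise_scale
  if (sd_majority == 0) {
    noise_sd <- c(majority = 0, minority = 0, other = 0)
  } else {
    v_majority <- v_det[["majority"]] + sd_majority^2
    min_noise_var <- config$group_variance_ratio * v_majority - v_det[["minority"]]
    if (min_noise_var < 0) {
      abort(paste0("Infeasible configuration: the minority signal variance ",
                   "already exceeds the targeted total variance; increase ",
                   "`noise_sd` or `group_variance_ratio`."))
    }
    noise_sd <- c(majority = sd_majority, minority = sqrt(min_noise_var),
                  other = sd_majority)
  }

  eps <- with_seed(derive_seeds(config$seed, seed_offset)[seed_offset],
                   rnorm(n) * unname(noise_sd[group]))
  list(y_signal = y_signal, y = y_signal + eps, noise_sd = noise_sd)
}

#' Population edge-behavior association under the generative model
#'
#' Closed-form population covariance between each FC edge and the behavioral
#' score for one group: `Sigma0 w_group + Gamma V_x (Gamma' w_group + gamma)`,
#' where `Sigma0` is the shared latent edge covariance, `Gamma` the
#' confound-to-edge loadings and `gamma` the confound-to-score loadings.
#' This is the oracle against which recovered association maps are compared.
#'
#' @param config A [synth_config()].
#' @param group `"majority"`, `"minority"` or `"other"` (the latter shares the
#'   majority pattern).
#' @return A tibble with columns `edge` and `association`.
#' @export
ground_truth_association <- function(config, group) {
  stopifnot(inherits(config, "synth_config"))
  w_of <- list(majority = config$w_majority, minority = config$w_minority,
               other = config$w_majority)
  if (!is.character(group) || length(group) != 1 || !group %in% names(w_of)) {
    abort("`group` must be one of \"majority\", \"minority\", \"other\".")
  }
  w <- w_of[[group]]
  lat <- config$latent
  vx <- confound_variances()
  gamma <- config$confound_loadings$y
  assoc <- drop(lat$A %*% crossprod(lat$A, w)) + lat$d * w +
    drop(lat$Gamma %*% (vx * (drop(crossprod(lat$Gamma, w)) + gamma)))
  tibble::tibble(edge = seq_along(assoc), association = assoc)
}

#' Simulate ROI time series for one subject
#'
#' Produces `runs_per_subject` runs of multivariate Gaussian ROI time series
#' whose population correlation matrix equals the subject's assigned FC
#' (back-transformed from Fisher z and projected to the nearest valid
#' correlation matrix when needed), together with per-frame FD and DVARS
#' traces. Motion spikes occur independently per frame at
#' `motion_params$spike_rate`: at a spike the frame's signal is inflated by
#' `spike_scale` (which drives DVARS) and FD jumps from its 0 baseline to
#' `fd_spike`.
#'
#' @param data A `synth_dataset`.
#' @param subject_id A subject identifier present in `data`.
#' @param config The generating [synth_config()]; defaults to the one
#'   attached to `data`.
#' @return A list of `run_timeseries` objects, each with elements `signal`
#'   (frames x ROI), `fd` and `dvars`.
#' @export
generate_timeseries <- function(data, subject_id, config = attr(data, "config")) {
  stopifnot(inherits(config, "synth_config"))
  row <- match(subject_id, data$subject_id)
  if (is.na(row)) abort(sprintf("Unknown subject_id `%s`.", subject_id))
  R <- tanh(devectorize_rsfc(data$fc[row, ]))
  diag(R) <- 1
  R <- nearest_correlation(R)
  U <- chol(R)
  mp <- config$motion_params
  runs <- vector("list", config$runs_per_subject)
  for (r in seq_len(config$runs_per_subject)) {
    seed_r <- (config$seed + 7919L * row + 104729L * r) %% 2147483629L
    runs[[r]] <- with_seed(seed_r, {
      nf <- config$frames_per_run
      signal <- matrix(rnorm(nf * config$n_roi), nf, config$n_roi) %*% U
      spikes <- runif(nf) < mp$spike_rate
      if (any(spikes)) {
        signal[spikes, ] <- signal[spikes, , drop = FALSE] * mp$spike_scale
      }
      fd <- ifelse(spikes, mp$fd_spike, 0)
      structure(list(signal = signal, fd = fd, dvars = compute_dvars(signal)),
                class = "run_timeseries")
    })
  }
  runs
}

# Eigenvalue-clipped projection to a valid correlation matrix.
nearest_correlation <- function(R, floor = 1e-4) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}
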