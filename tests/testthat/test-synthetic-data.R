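test_that("generation is deterministic and honors the configured structure", {
  cfg <- tiny_config(seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)

  expect_equal(unname(table(d1$group)[c("majority", "minority")]),
               c(cfg$n_majority, cfg$n_minority), ignore_attr = TRUE)
  expect_equal(ncol(d1$fc), cfg$n_edges)
  # family members share a site, always
  expect_true(all(tapply(d1$site, d1$family,
                         function(s) length(unique(s)) == 1)))
  # weight pair correlation equals the configured pattern similarity
  for (rho in c(-0.5, 0, 0.3, 1)) {
    cfg_r <- tiny_config(seed = 3, pattern_similarity = rho)
    expect_equal(cor(cfg_r$w_majority, cfg_r$w_minority), rho,
                 tolerance = 1e-6)
  }
})

test_that("noiseless scores equal the group-pattern dot product exactly", {
  cfg <- tiny_config(seed = 5, noise_sd = 0, group_mean_shift = 0.4)
  d <- generate_dataset(cfg)
  tr <- attr(d, "truth")
  for (i in c(1, 25, 61, 80)) {
    w <- if (d$group[i] == "minority") tr$w_minority else tr$w_majority
    shift <- if (d$group[i] == "minority") 0.4 else 0
    expect_equal(d$y[i], sum(d$fc[i, ] * w) + shift, tolerance = 1e-12)
  }
})

test_that("noise tuned for R^2 = 0.5 gives the implied signal correlation", {
  cfg <- synth_config(n_majority = 400, n_minority = 100, n_roi = 40, seed = 2)
  cfg2 <- synth_config(n_majority = 400, n_minority = 100, n_roi = 40,
                       seed = 2, noise_sd = noise_sd_for_r2(cfg, 0.5))
  d <- generate_dataset(cfg2)
  mj <- d$group == "majority"
  r <- cor(d$y[mj], d$fc[mj, ] %*% attr(d, "truth")$w_majority)
  expect_gt(r, 0.6)
  expect_lt(r, 0.8)
})

test_that("ground-truth association matches a Monte-Carlo covariance oracle", {
  cfg <- synth_config(n_majority = 100000, n_minority = 1, n_roi = 10,
                      seed = 9, noise_sd = 0.1)
  d <- generate_dataset(cfg)
  mj <- d$group == "majority"
  emp <- fairconn:::pop_cov_vec(d$fc[mj, ], d$y[mj])
  truth <- ground_truth_association(cfg, "majority")$association
  expect_lt(max(abs(emp - truth)), 0.02)
  # identity-free sanity: with similarity 1 the two group oracles coincide
  cfg1 <- tiny_config(seed = 2, pattern_similarity = 1)
  expect_equal(ground_truth_association(cfg1, "majority")$association,
               ground_truth_association(cfg1, "minority")$association)
  expect_error(ground_truth_association(cfg1, "martian"), "group")
})

test_that("behavioral variance targeting calibrates the Levene null", {
  reject <- logical(400)
  for (i in seq_len(400)) {
    cfg <- synth_config(n_majority = 60, n_minority = 60, n_roi = 8,
                        seed = 5000 + i, group_variance_ratio = 1)
    d <- generate_dataset(cfg)
    lev <- levene_test(d$y[d$group == "majority"],
                       d$y[d$group == "minority"])
    reject[i] <- lev$p_value <= 0.05
  }
  expect_lte(mean(reject), 0.07)
})

test_that("variance ratio is hit in population and reflected in samples", {
  cfg <- synth_config(n_majority = 4000, n_minority = 4000, n_roi = 10,
                      seed = 21, group_variance_ratio = 2)
  d <- generate_dataset(cfg)
  ratio <- var(d$y[d$group == "minority"]) / var(d$y[d$group == "majority"])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  # infeasible targeting is refused, not silently clamped
  cfg_bad <- synth_config(n_majority = 50, n_minority = 50, n_roi = 10,
                          seed = 3, pattern_similarity = 0,
                          noise_sd = 0.001, group_variance_ratio = 0.01)
  expect_error(generate_dataset(cfg_bad), "Infeasible")
})

test_that("behavior suites share structure but have per-behavior truths", {
  cfg <- tiny_config(seed = 8)
  suite <- generate_behavior_suite(cfg, c(0.2, 0.9))
  expect_true(all(c("y_1", "y_2") %in% names(suite)))
  truth <- attr(suite, "truth")
  expect_equal(cor(truth[[1]]$w_majority, truth[[1]]$w_minority), 0.2,
               tolerance = 1e-6)
  expect_equal(cor(truth[[2]]$w_majority, truth[[2]]$w_minority), 0.9,
               tolerance = 1e-6)
  # same FC as the single-behavior dataset with the same seed
  expect_equal(suite$fc, generate_dataset(cfg)$fc)
})

test_that("simulated time series realize the assigned FC and motion model", {
  cfg <- synth_config(n_majority = 4, n_minority = 2, n_roi = 10, seed = 13,
                      frames_per_run = 10000, runs_per_subject = 1,
                      motion_params = list(spike_rate = 0, fd_spike = 0.8,
                                           spike_scale = 6))
  d <- generate_dataset(cfg)
  runs <- generate_timeseries(d, d$subject_id[1])
  expect_identical(runs, generate_timeseries(d, d$subject_id[1]))
  expect_true(all(runs[[1]]$fd == 0))  # no spikes at rate 0
  z <- compute_rsfc(runs)
  expect_lt(max(abs(vectorize_rsfc(z) - d$fc[1, ])), 0.05)

  cfg_m <- synth_config(n_majority = 4, n_minority = 2, n_roi = 8, seed = 13,
                        frames_per_run = 400, runs_per_subject = 2,
                        motion_params = list(spike_rate = 0.1, fd_spike = 0.8,
                                             spike_scale = 6))
  dm <- generate_dataset(cfg_m)
  runs_m <- generate_timeseries(dm, dm$subject_id[1])
  expect_length(runs_m, 2)
  expect_true(any(runs_m[[1]]$fd > 0.3))
  spikes <- runs_m[[1]]$fd > 0
  # signal inflation at spikes drives DVARS above the clean baseline
  expect_gt(mean(runs_m[[1]]$dvars[spikes][-1], na.rm = TRUE),
            mean(runs_m[[1]]$dvars[!spikes][-1]))
})
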