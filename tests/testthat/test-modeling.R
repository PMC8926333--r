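test_that("confound regression equals a normal-equation oracle and is train-only", {
  set.seed(3)
  n <- 40
  d <- tibble::tibble(subject_id = as.character(1:n), age = rnorm(n),
                      motion = rnorm(n), gender = rbinom(n, 1, 0.5))
  d$fc <- matrix(rnorm(n * 12), n, 12)
  d$y <- 2 * d$age + rnorm(n)
  cm <- fit_confound_model(d, c("age", "motion", "gender"))
  # brute-force least squares for the behavioral target and one edge
  X <- cbind(1, d$age, d$motion, d$gender)
  expect_equal(unname(cm$beta_y),
               drop(solve(crossprod(X), crossprod(X, d$y))),
               tolerance = 1e-8)
  expect_equal(unname(cm$beta_fc[, 5]),
               drop(solve(crossprod(X), crossprod(X, d$fc[, 5]))),
               tolerance = 1e-8)

  # training residuals are orthogonal to every confound
  res <- apply_confound_model(cm, d)
  for (v in c("age", "motion", "gender")) {
    expect_lt(abs(cor(res$y, d[[v]])), 1e-10)
    expect_lt(abs(cor(res$fc[, 3], d[[v]])), 1e-10)
  }
  # y = 2 * age exactly: coefficient 2, residuals 0
  d2 <- d
  d2$y <- 2 * d2$age
  cm2 <- fit_confound_model(d2, c("age", "motion", "gender"))
  expect_equal(unname(cm2$beta_y["age"]), 2, tolerance = 1e-10)
  expect_lt(max(abs(apply_confound_model(cm2, d2)$y)), 1e-10)

  # zero-coefficient model is the identity transform
  cm0 <- cm
  cm0$beta_y[] <- 0
  cm0$beta_fc[] <- 0
  same <- apply_confound_model(cm0, d)
  expect_equal(same$y, d$y)
  expect_equal(same$fc, d$fc)

  # collinear confounds are named in the error
  d3 <- d
  d3$age2 <- d3$age
  expect_error(fit_confound_model(d3, c("age", "age2")), "age2")
  expect_error(fit_confound_model(d[1:3, ], c("age", "motion", "gender")),
               "training subjects")
})

test_that("the correlation kernel matches per-pair correlation elementwise", {
  set.seed(5)
  a <- matrix(rnorm(50), 5, 10)
  b <- matrix(rnorm(40), 4, 10)
  K <- correlation_kernel(a, b)
  for (s in 1:5) {
    for (i in 1:4) expect_equal(K[s, i], cor(a[s, ], b[i, ]), tolerance = 1e-12)
  }
  Ka <- correlation_kernel(a)
  expect_equal(Ka, t(Ka))
  expect_equal(diag(Ka), rep(1, 5))
  expect_error(correlation_kernel(rbind(rep(1, 10)), b), "Zero-variance")
  expect_error(correlation_kernel(a, matrix(1, 2, 9)), "Edge counts")
})

test_that("kernel ridge solves (K + lambda I) alpha = y exactly", {
  # identity kernel, lambda 1: alpha = y / 2
  y <- c(1, -2, 3)
  f <- fit_krr(diag(3), y, 1)
  expect_equal(f$dual_coefficients, y / 2)

  set.seed(6)
  X <- matrix(rnorm(15 * 8), 15, 8)
  K <- tcrossprod(X)
  y <- rnorm(15)
  f2 <- fit_krr(K, y, 0.7)
  expect_equal(f2$dual_coefficients,
               drop(solve(K + 0.7 * diag(15)) %*% y), tolerance = 1e-8)
  # heavy regularization drives alpha to y / lambda and predictions to 0
  f3 <- fit_krr(K, y, 1e9)
  expect_equal(f3$dual_coefficients, y / 1e9, tolerance = 1e-6)
  expect_lt(max(abs(predict_krr(f3, K))), 1e-5)

  # prediction is the plain matrix product; duplicates stay duplicates
  Kt <- matrix(rnorm(30), 2, 15)
  expect_equal(predict_krr(f2, Kt), drop(Kt %*% f2$dual_coefficients))
  expect_equal(predict_krr(f2, rbind(Kt[1, ], Kt[1, ]))[1],
               predict_krr(f2, rbind(Kt[1, ], Kt[1, ]))[2])
  expect_equal(predict_krr(f2, matrix(0, 1, 15)), 0)
  expect_error(fit_krr(K, y, 0), "lambda")
  expect_error(fit_krr(K, y[1:3], 1), "conformable")
})

test_that("linear ridge agrees with OLS at small lambda and with its dual", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, 5)   # tall, full rank
  y <- drop(X %*% c(1, -1, 2, 0, 0.5)) + rnorm(60, sd = 0.1)
  w_ols <- drop(solve(crossprod(X), crossprod(X, y)))
  f <- fit_linear_ridge(X, y, 1e-8)
  expect_equal(f$coefficients, w_ols, tolerance = 1e-6)

  # wide X: primal-dual identity against kernel ridge with linear kernel
  Xw <- matrix(rnorm(12 * 30), 12, 30)
  yw <- rnorm(12)
  lam <- 2.5
  fw <- fit_linear_ridge(Xw, yw, lam)
  fk <- fit_krr(tcrossprod(Xw), yw, lam)
  expect_equal(predict_linear_ridge(fw, Xw), predict_krr(fk, tcrossprod(Xw)),
               tolerance = 1e-8)
  Xtest <- matrix(rnorm(4 * 30), 4, 30)
  expect_equal(predict_linear_ridge(fw, Xtest),
               predict_krr(fk, Xtest %*% t(Xw)), tolerance = 1e-8)

  # y in the column span with tiny lambda: near-zero training residuals
  ys <- drop(Xw %*% rnorm(30))
  fs <- fit_linear_ridge(Xw, ys, 1e-10)
  expect_lt(max(abs(predict_linear_ridge(fs, Xw) - ys)), 1e-5)
})

test_that("inner cross-validation picks a sensible penalty deterministically", {
  cfg <- synth_config(n_majority = 90, n_minority = 30, n_roi = 12, seed = 8,
                      noise_sd = 0.02)
  d <- generate_dataset(cfg)
  expect_equal(nested_cv_select_lambda(d, grid = 3)$lambda, 3)
  # a grossly oversmoothed competitor loses to the sensible penalty
  sel <- nested_cv_select_lambda(d, grid = c(2, 2e6), inner_folds = 5,
                                 seed = 4)
  expect_equal(sel$lambda, 2)
  sel2 <- nested_cv_select_lambda(d, grid = c(2, 2e6), inner_folds = 5,
                                  seed = 4)
  expect_identical(sel, sel2)
  expect_error(nested_cv_select_lambda(d, grid = numeric()), "non-empty")
})

test_that("training-arm subsampling equalizes group counts site by site", {
  set.seed(9)
  d <- tibble::tibble(
    subject_id = as.character(1:24),
    group = c(rep("minority", 5), rep("majority", 9),
              rep("minority", 5), rep("majority", 3),
              rep("other", 2)),
    site = c(rep("s1", 14), rep("s2", 8), rep("s1", 2)))
  # site s1: 5 minority, 9 majority -> 5 of each; s2: 5 vs 3 -> 3 of each
  mo <- subsample_training_population(d, "majority_only", seed = 1)
  expect_equal(unname(table(mo$site)), c(5L, 3L), ignore_attr = TRUE)
  expect_true(all(mo$group == "majority"))
  mi <- subsample_training_population(d, "minority_only", seed = 1)
  expect_equal(unname(table(mi$site)), c(5L, 3L), ignore_attr = TRUE)
  expect_true(all(mi$group == "minority"))
  ba <- subsample_training_population(d, "balanced", seed = 1)
  expect_equal(sum(ba$group == "minority"), sum(ba$group == "majority"))
  expect_equal(nrow(ba), 16)
})

test_that("end-to-end prediction recovers noiseless signal and fails on nulls", {
  cfg <- synth_config(n_majority = 400, n_minority = 100, n_roi = 40,
                      seed = 10, noise_sd = 0, pattern_similarity = 1,
                      latent_share = 0.95)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 2, n_iter = 5,
                                   n_splits = 1, seed = 2,
                                   exclude_hard = FALSE)
  pr <- run_prediction(d, des, lambda_grid = c(0.1, 10), inner_folds = 3,
                       seed = 3)
  acc <- summarize_groups(pr)
  expect_gt(mean(acc$predictive_cod), 0.9)

  # permuted behavior: accuracy collapses to about zero
  d_null <- d
  set.seed(11)
  d_null$y <- sample(d_null$y)
  pr_null <- run_prediction(d_null, des, lambda_grid = 5, seed = 3)
  p <- pr_null$predictions
  expect_lt(abs(cor(p$y_true, p$y_pred)), 0.15)

  # deterministic given the seed
  pr2 <- run_prediction(d, des, lambda_grid = c(0.1, 10), inner_folds = 3,
                        seed = 3)
  expect_equal(pr$predictions, pr2$predictions)
})

test_that("a test-only confound cannot inflate accuracy (leakage tripwire)", {
  cfg <- synth_config(n_majority = 120, n_minority = 40, n_roi = 10,
                      seed = 12)
  cfg2 <- synth_config(n_majority = 120, n_minority = 40, n_roi = 10,
                       seed = 12, noise_sd = noise_sd_for_r2(cfg, 1e-6))
  d <- generate_dataset(cfg2)  # essentially unpredictable behavior
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 2, n_iter = 5,
                                   n_splits = 1, seed = 5,
                                   exclude_hard = FALSE)
  # plant a confound that predicts y on the test folds only
  d$oracle <- d$y
  fold_of <- setNames(des$splits[[1]]$fold_of_subject$fold,
                      des$splits[[1]]$fold_of_subject$subject_id)
  train1 <- names(fold_of)[fold_of != 1]
  set.seed(6)
  d$oracle[match(train1, d$subject_id)] <- rnorm(length(train1))
  pr <- run_prediction(d, des, confounds = c("age", "oracle"),
                       lambda_grid = 5, seed = 7)
  p1 <- pr$predictions[pr$predictions$division == 1, ]
  expect_lt(cor(p1$y_true, p1$y_pred), 0.25)
})

test_that("the multisite scheme enumerates all choose(10, 3) divisions", {
  cfg <- synth_config(n_majority = 420, n_minority = 200, n_roi = 10,
                      seed = 6, n_sites = 10)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_design_abcd(d, spec, n_folds = 10)
  pr <- run_prediction(d, des, lambda_grid = 5, seed = 1)
  expect_equal(nrow(pr$divisions), choose(10, 3))
  expect_equal(length(unique(pr$divisions$test_fold_set)), 120)
  # every site sits wholly inside one fold
  fo <- des$splits[[1]]$fold_of_subject
  site_of <- d$site[match(fo$subject_id, d$subject_id)]
  expect_true(all(tapply(fo$fold, site_of,
                         function(f) length(unique(f)) == 1)))
})
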