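test_that("SST is the population variance of pooled training scores", {
  expect_equal(training_sst(c(0, 2)), 1)
  expect_error(training_sst(rep(3, 5)), "Constant")
  expect_error(training_sst(1), "2 training")
  set.seed(1)
  y <- rnorm(20)
  expect_equal(training_sst(3 * y + 7), 9 * training_sst(y))
})

test_that("predictive COD follows the printed definition, sign included", {
  expect_equal(predictive_cod(c(1, 2, 3), c(1, 2, 3), 2), 1)
  expect_equal(predictive_cod(c(0, 2), c(1, 1), 1), 0)      # SSE = 1
  expect_equal(predictive_cod(c(0, 0), c(2, 2), 1), -3)     # SSE = 4
  expect_error(predictive_cod(1:3, 1:2, 1), "Length")
  expect_error(predictive_cod(1:3, 1:3, 0), "sst")
  # antitone in SSE at fixed SST
  y <- c(0, 1, 2, 3)
  expect_gt(predictive_cod(y, y + 0.1, 1), predictive_cod(y, y + 0.5, 1))
})

test_that("Pearson accuracy is affine-invariant where COD is not", {
  y <- c(1, 3, 2, 5, 4)
  yh <- c(1.2, 2.9, 2.2, 4.7, 4.1)
  expect_equal(pearson_accuracy(y, y), 1)
  expect_equal(pearson_accuracy(y, -y), -1)
  expect_equal(pearson_accuracy(y, yh + 100), pearson_accuracy(y, yh))
  sst <- training_sst(y)
  expect_lt(predictive_cod(y, yh + 100, sst), predictive_cod(y, yh, sst))
  expect_warning(r <- pearson_accuracy(y, rep(1, 5)), "Constant")
  expect_true(is.na(r))
  expect_error(pearson_accuracy(1:2, 1:2), "n >= 3")
})

test_that("prediction shift is the squared mean signed error", {
  expect_equal(prediction_shift(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(prediction_shift(c(0, 0), c(2, 2)), 4)
  expect_equal(prediction_shift(c(1, 1, 1), c(2, 0, 4)), 1)  # residuals 1,-1,3
  expect_equal(prediction_shift(c(1, -1), c(-1, 1)), 0)      # residuals sum 0
  expect_error(prediction_shift(numeric(), numeric()), "Empty")
})

test_that("Levene W matches hand computation and calibrates under the null", {
  x <- c(-1, 0, 1, 2)
  expect_equal(levene_test(x, x)$statistic, 0)
  expect_equal(levene_test(x, x)$p_value, 1)
  # degenerate constant absolute deviations with different levels
  deg <- levene_test(c(-1, 1), c(-3, 3))
  expect_equal(deg$statistic, Inf)
  expect_equal(deg$p_value, 0)
  # hand-sized check against the W formula via one-way ANOVA on |dev|
  set.seed(2)
  a <- rnorm(8)
  b <- rnorm(6, sd = 2)
  z <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(1:2, c(8, 6)))
  w_aov <- summary(stats::aov(z ~ g))[[1]]$`F value`[1]
  expect_equal(levene_test(a, b)$statistic, w_aov, tolerance = 1e-10)
  # null calibration
  set.seed(3)
  rej <- replicate(500, {
    levene_test(rnorm(200), rnorm(200))$p_value <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("group summaries aggregate the component metrics faithfully", {
  cfg <- synth_config(n_majority = 120, n_minority = 40, n_roi = 10, seed = 4)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 2, n_iter = 5,
                                   n_splits = 2, seed = 1,
                                   exclude_hard = FALSE)
  pr <- run_prediction(d, des, lambda_grid = 5, seed = 2)
  by_div <- summarize_groups(pr, by_division = TRUE)
  # every division-level row matches a direct recomputation
  preds <- pr$predictions[!is.na(pr$predictions$pair_id), ]
  for (k in seq_len(nrow(by_div))) {
    rows <- preds[preds$division == by_div$division[k] &
                    preds$group == by_div$group[k], ]
    sst <- pr$divisions$sst_matched[pr$divisions$division ==
                                      by_div$division[k]]
    expect_equal(by_div$sse[k], mean((rows$y_true - rows$y_pred)^2))
    expect_equal(by_div$predictive_cod[k],
                 predictive_cod(rows$y_true, rows$y_pred, sst))
    expect_equal(by_div$pearson_r[k],
                 pearson_accuracy(rows$y_true, rows$y_pred))
    expect_equal(by_div$prediction_shift[k],
                 prediction_shift(rows$y_true, rows$y_pred))
  }
  # split-level values are the fold means of the division-level values
  split_level <- summarize_groups(pr)
  m1 <- by_div[by_div$split == 1 & by_div$group == "minority", ]
  expect_equal(
    split_level$predictive_cod[split_level$split == 1 &
                                 split_level$group == "minority"],
    mean(m1$predictive_cod))
})

test_that("a pure mean shift moves COD by -delta^2/SST and leaves r alone", {
  cfg <- synth_config(n_majority = 120, n_minority = 40, n_roi = 10, seed = 7)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 2, n_iter = 5,
                                   n_splits = 1, seed = 1,
                                   exclude_hard = FALSE)
  pr <- run_prediction(d, des, lambda_grid = 5, seed = 2)
  delta <- 0.3
  preds <- pr$predictions[!is.na(pr$predictions$pair_id), ]
  for (dv in unique(preds$division)) {
    rows <- preds[preds$division == dv & preds$group == "minority", ]
    sst <- pr$divisions$sst_matched[pr$divisions$division == dv]
    base_cod <- predictive_cod(rows$y_true, rows$y_pred, sst)
    shifted_cod <- predictive_cod(rows$y_true, rows$y_pred + delta, sst)
    shift_term <- delta^2 + 2 * delta * mean(rows$y_pred - rows$y_true)
    expect_equal(shifted_cod - base_cod, -shift_term / sst,
                 tolerance = 1e-12)
    # for centered residuals the change is exactly -delta^2 / sst
    centered <- rows$y_pred - mean(rows$y_pred - rows$y_true)
    expect_equal(predictive_cod(rows$y_true, centered + delta, sst) -
                   predictive_cod(rows$y_true, centered, sst),
                 -delta^2 / sst, tolerance = 1e-12)
    expect_equal(pearson_accuracy(rows$y_true, rows$y_pred + delta),
                 pearson_accuracy(rows$y_true, rows$y_pred),
                 tolerance = 1e-12)
  }
})

test_that("raising one group's score variance lowers its COD in expectation", {
  set.seed(8)
  diffs <- replicate(200, {
    n <- 80
    sst <- 1
    y1 <- rnorm(n)
    y2 <- rnorm(n, sd = 1.6)
    r <- 0.6
    yh1 <- r * y1 + rnorm(n, sd = sqrt(1 - r^2))
    yh2 <- r * y2 + rnorm(n, sd = 1.6 * sqrt(1 - r^2))
    predictive_cod(y2, yh2, sst) - predictive_cod(y1, yh1, sst)
  })
  expect_lt(mean(diffs), 0)
})
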