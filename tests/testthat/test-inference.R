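test_that("block permutation respects families and detects strong signal", {
  set.seed(1)
  fam <- rep(sprintf("f%02d", 1:40), sample(1:3, 40, replace = TRUE))
  n <- length(fam)
  y <- rnorm(n)
  # perfect predictions: p at the add-one floor
  r <- block_permutation_predictability(y, y, blocks = fam, n_perm = 200,
                                        seed = 3)
  expect_equal(r$p, 1 / 201)
  expect_length(r$null_values, 200)
  expect_identical(r$null_values,
                   block_permutation_predictability(y, y, blocks = fam,
                                                    n_perm = 200,
                                                    seed = 3)$null_values)
  # permuted indices always preserve block structure and sizes
  for (i in 1:50) {
    p <- fairconn:::block_permute_indices(fam)
    expect_equal(sort(p), seq_len(n))
    expect_true(all(tapply(fam[p], fam, function(v) length(unique(v)) == 1)))
    expect_equal(unname(tapply(p, fam, length)),
                 unname(tapply(seq_len(n), fam, length)))
  }
  # strata confine blocks: a block never leaves its stratum
  strat <- rep(c("a", "b"), length.out = 40)[match(fam, unique(fam))]
  rs <- block_permutation_predictability(y, rnorm(n), blocks = fam,
                                         n_perm = 50, seed = 2,
                                         strata = strat)
  expect_s3_class(rs, "permutation_result")
  expect_error(block_permutation_predictability(
    y, y, blocks = fam, strata = sample(c("a", "b"), n, TRUE), seed = 1),
    "single stratum")
  # all-singleton blocks reduce to an ordinary permutation: every index
  # can move anywhere, and the test stays calibrated on independent data
  expect_false(all(fairconn:::block_permute_indices(1:30) == 1:30) &&
                 all(fairconn:::block_permute_indices(1:30) == 1:30))
  set.seed(10)
  rej <- replicate(200, {
    block_permutation_predictability(rnorm(40), rnorm(40), blocks = 1:40,
                                     n_perm = 150,
                                     seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.09)
})

test_that("flip-label test is exact on exchangeable pairs and powerful on gaps", {
  set.seed(2)
  m <- 50
  same <- tibble::tibble(y_true_a = rnorm(m), y_pred_a = rnorm(m))
  same$y_true_b <- same$y_true_a
  same$y_pred_b <- same$y_pred_a
  met <- function(y, yhat) predictive_cod(y, yhat, 1)
  r0 <- flip_label_test(same, met, n_perm = 200, seed = 4)
  expect_equal(r0$observed, 0)
  expect_gt(r0$p, 0.9)

  # large injected COD gap: p at the floor, for both shuffle variants
  gap <- tibble::tibble(y_true_a = rnorm(100), y_pred_a = 0,
                        y_true_b = rnorm(100))
  gap$y_pred_b <- gap$y_true_b
  r1 <- flip_label_test(gap, met, n_perm = 400, seed = 5)
  expect_equal(r1$p, 1 / 401)
  expect_lt(r1$observed, 0)
  r1p <- flip_label_test(gap, met, n_perm = 400, seed = 5, pairwise = TRUE)
  expect_equal(r1p$p, 1 / 401)

  # null distribution is symmetric about zero under exchangeability
  iid <- tibble::tibble(y_true_a = rnorm(60), y_pred_a = rnorm(60),
                        y_true_b = rnorm(60), y_pred_b = rnorm(60))
  rn <- flip_label_test(iid, met, n_perm = 2000, seed = 6)
  expect_lt(abs(mean(rn$null_values)), 3 * sd(rn$null_values) / sqrt(2000))

  # type-I calibration on iid exchangeable pairs
  set.seed(7)
  rej <- replicate(300, {
    p <- tibble::tibble(y_true_a = rnorm(40), y_pred_a = rnorm(40),
                        y_true_b = rnorm(40), y_pred_b = rnorm(40))
    flip_label_test(p, met, n_perm = 150, seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
  expect_error(flip_label_test(iid[1, ], met), "2 matched pairs")
})

test_that("BH control matches hand computation and a brute-force scan", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.5), 0.05), c(TRUE, TRUE, FALSE))
  expect_false(any(fdr_bh(rep(1, 4), 0.05)))
  expect_true(fdr_bh(0.04, 0.05))
  expect_equal(fdr_bh(numeric()), logical())
  expect_error(fdr_bh(c(0.5, 0)), "p-values")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(fdr_bh(p, 0.05), brute_force_bh(p, 0.05))
  }
})

test_that("predictability classification applies both criteria strictly", {
  tab <- tibble::tibble(
    behavior = c("strong", "negative", "null", "boundary"),
    p_perm = c(0.001, 0.001, 0.8, 0.001),
    mean_acc_minority = c(0.2, -0.1, -0.05, 0.1),
    mean_acc_majority = c(0.3, -0.2, 0.01, 0.1),
    mean_r = c(0.4, 0.3, 0.01, 0.15))
  out <- classify_predictable(tab)
  expect_true(out$predictable[out$behavior == "strong"])
  expect_false(out$predictable[out$behavior == "negative"])  # both groups <= 0
  expect_false(out$predictable[out$behavior == "null"])      # fails FDR
  # r = 0.15 exactly is excluded by the strict inequality
  expect_true(out$predictable[out$behavior == "boundary"])
  expect_false(out$headline[out$behavior == "boundary"])
  expect_true(out$headline[out$behavior == "strong"])
  expect_error(classify_predictable(tab[, 1:2]), "columns")
})
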