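test_that("assignment cost equals the exhaustive-search minimum", {
  # spec'd micro-instances
  r <- hungarian_match(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(r$assignment, c(1L, 2L))
  expect_equal(r$total_cost, 2)
  expect_equal(hungarian_match(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))$total_cost, 0)

  set.seed(10)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    m <- n + sample(0:2, 1)
    cost <- matrix(sample(0:30, n * m, replace = TRUE), n, m)
    h <- hungarian_match(cost)
    expect_equal(h$total_cost, brute_force_assignment(cost))
    expect_false(anyDuplicated(h$assignment) > 0)
  }
  # rectangular spec example: 5 x 7
  cost57 <- matrix(sample(0:50, 35, replace = TRUE), 5, 7)
  expect_equal(hungarian_match(cost57)$total_cost,
               brute_force_assignment(cost57))
  expect_error(hungarian_match(matrix(1, 3, 2)), "rows <= columns")
})

test_that("cost matrices sum standardized differences with exact-match gates", {
  a <- tibble::tibble(subject_id = "m1", age = 1, gender = 0, y = 5)
  b <- tibble::tibble(subject_id = c("w1", "w2"), age = c(1, 2),
                      gender = c(0, 1), y = c(5, 5))
  spec <- match_cost_spec(c("age", "gender", "y"),
                          categorical_vars = "gender")
  cost <- compute_cost_matrix(a, b, spec)
  expect_equal(cost[1, 1], 0)                       # identical subjects
  expect_equal(cost[1, 2], spec$infeasible_cost)    # gender mismatch

  # unstandardized single variable: |1.0 - 3.5| = 2.5
  spec_raw <- match_cost_spec("y", standardize = FALSE)
  cost_raw <- compute_cost_matrix(tibble::tibble(y = 1.0),
                                  tibble::tibble(y = 3.5), spec_raw)
  expect_equal(cost_raw[1, 1], 2.5)

  # standardization makes the cost scale-free
  set.seed(1)
  a2 <- tibble::tibble(y = rnorm(5))
  b2 <- tibble::tibble(y = rnorm(7))
  spec_std <- match_cost_spec("y")
  expect_equal(compute_cost_matrix(a2, b2, spec_std),
               compute_cost_matrix(dplyr::mutate(a2, y = 100 * y),
                                   dplyr::mutate(b2, y = 100 * y), spec_std))
  expect_error(compute_cost_matrix(a2, tibble::tibble(z = 1), spec_std),
               "missing")
})

test_that("iterative within-site matching pairs, excludes and terminates", {
  set.seed(2)
  mk <- function(n_min, n_maj, site = "s1") {
    tibble::tibble(
      subject_id = paste0(site, "_", seq_len(n_min + n_maj)),
      group = rep(c("minority", "majority"), c(n_min, n_maj)),
      site = site, age = rnorm(n_min + n_maj), y = rnorm(n_min + n_maj))
  }
  spec <- match_cost_spec(c("age", "y"))

  # one compatible pair
  one <- mk(2, 2)
  r1 <- iterative_site_match(one, spec)
  expect_lte(nrow(r1$pairs), 2)
  expect_true(all(r1$pairs$minority_id %in%
                    one$subject_id[one$group == "minority"]))

  # pigeonhole: 4 minority vs 2 majority gives <= 2 pairs, >= 2 exclusions
  r2 <- iterative_site_match(mk(4, 2), spec)
  expect_lte(nrow(r2$pairs), 2)
  expect_gte(nrow(r2$exclusions), 2)

  # the per-round matching cost never increases; a large site keeps a
  # sizeable matched set when each drop is a small share of the total
  big <- mk(70, 180)
  r3 <- iterative_site_match(big, spec)
  expect_true(all(diff(r3$cost_by_round$total_cost) <= 1e-9))
  expect_gt(nrow(r3$pairs), 2)
  # every round drops the mandatory highest-cost minority
  expect_true(any(r3$exclusions$reason == "highest_cost"))

  # a site lacking one group yields no pairs but only a warning
  lone <- dplyr::filter(mk(3, 3), group == "minority")
  expect_warning(r4 <- iterative_site_match(lone, spec), "lacks")
  expect_equal(nrow(r4$pairs), 0)
})

test_that("site merging follows the deterministic greedy trace", {
  r <- merge_sites_to_folds(c(a = 30, b = 30, c = 30), 3)
  totals <- tapply(c(a = 30, b = 30, c = 30)[r$site], r$fold, sum)
  expect_equal(as.numeric(totals), rep(30, 3))

  # hand trace of largest-first greedy: 8,7,5 seed the folds; 4 -> fold of 5
  # (9); 3 -> fold of 7 (10); 3 -> fold of 8 (11)
  counts <- c(s1 = 8, s2 = 7, s3 = 5, s4 = 4, s5 = 3, s6 = 3)
  r2 <- merge_sites_to_folds(counts, 3)
  totals2 <- sort(as.numeric(tapply(counts[r2$site], r2$fold, sum)))
  expect_equal(totals2, c(9, 10, 11))

  expect_equal(unique(merge_sites_to_folds(counts, 1)$fold), 1L)
  expect_error(merge_sites_to_folds(c(a = 1), 2), "Fewer sites")
  expect_identical(merge_sites_to_folds(counts, 3), r2)  # deterministic
})

test_that("matched splits preserve families, avoid repetition, and reproduce", {
  cfg <- synth_config(n_majority = 120, n_minority = 40, n_roi = 10, seed = 3)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 4, n_iter = 10,
                                   n_splits = 2, seed = 9)
  expect_s3_class(des, "matched_design")
  expect_length(des$splits, 2)
  for (s in des$splits) {
    # no subject appears in two pairs of the same split
    ids <- c(s$pairs$minority_id, s$pairs$majority_id)
    expect_false(anyDuplicated(ids) > 0)
    # paired subjects belong to the designated groups
    expect_true(all(d$group[match(s$pairs$minority_id, d$subject_id)] ==
                      "minority"))
    expect_true(all(d$group[match(s$pairs$majority_id, d$subject_id)] ==
                      "majority"))
    # pairs are within fold and families never straddle folds
    fold_of <- setNames(s$fold_of_subject$fold, s$fold_of_subject$subject_id)
    expect_equal(unname(fold_of[s$pairs$minority_id]), s$pairs$fold)
    expect_equal(unname(fold_of[s$pairs$majority_id]), s$pairs$fold)
    expect_true(all(tapply(fold_of[d$subject_id], d$family,
                           function(f) length(unique(f)) == 1)))
    # exact-match variable agrees within every pair
    expect_equal(d$gender[match(s$pairs$minority_id, d$subject_id)],
                 d$gender[match(s$pairs$majority_id, d$subject_id)])
  }
  expect_identical(des, select_matched_splits_hcp(d, spec, n_folds = 4,
                                                  n_iter = 10, n_splits = 2,
                                                  seed = 9))

  # when every subject is identical on the matching variables, any
  # feasible draw achieves zero cost and the selected maximum is zero
  dup <- d
  dup$age <- 1
  dup$motion <- 0.5
  dup$gender <- 0
  dup$y2 <- 2
  spec0 <- match_cost_spec(c("age", "motion", "gender", "y2"),
                           categorical_vars = "gender")
  des0 <- select_matched_splits_hcp(dup, spec0, behavior = "y2",
                                    n_folds = 2, n_iter = 5,
                                    n_splits = 1, seed = 4,
                                    exclude_hard = FALSE)
  expect_lt(des0$splits[[1]]$max_fold_cost, 1e-12)
})

test_that("pair validation runs paired t tests with BH across the family", {
  cfg <- tiny_config(seed = 6)
  d <- generate_dataset(cfg)
  spec <- match_cost_spec(c("age", "motion", "gender", "y"),
                          categorical_vars = "gender")
  des <- select_matched_splits_hcp(d, spec, n_folds = 2, n_iter = 15,
                                   n_splits = 2, seed = 2,
                                   exclude_hard = FALSE)
  v <- validate_matching(d, des, c("age", "motion", "y"))
  expect_equal(nrow(v), 3 * 2)
  expect_true(all(v$p_value >= 0 & v$p_value <= 1))
  expect_equal(v$p_adjusted, p.adjust(v$p_value, "BH"))
  expect_equal(v$rejected, v$p_adjusted <= 0.05)

  # identical pairs: t = 0, p = 1 (degenerate zero-variance differences)
  d2 <- d
  des2 <- des
  des2$splits <- des2$splits[1]
  pr <- des2$splits[[1]]$pairs
  for (v2 in c("age", "motion", "y")) {
    d2[[v2]][match(pr$minority_id, d2$subject_id)] <-
      d2[[v2]][match(pr$majority_id, d2$subject_id)]
  }
  vd <- validate_matching(d2, des2, c("age", "y"))
  expect_true(all(vd$statistic == 0))
  expect_true(all(vd$p_value == 1))
  # constant nonzero differences warn but still return t = 0, p = 1
  d3 <- d2
  d3$age[match(pr$minority_id, d3$subject_id)] <-
    d3$age[match(pr$majority_id, d3$subject_id)] + 1
  expect_warning(v3 <- validate_matching(d3, des2, "age"), "Constant")
  expect_equal(v3$statistic, 0)
  expect_equal(v3$p_value, 1)
})

test_that("hard-to-match pre-pass flags only consistently costly subjects", {
  cfg <- tiny_config(seed = 14)
  d <- generate_dataset(cfg)
  # plant one impossible-to-match minority subject
  out_id <- d$subject_id[d$group == "minority"][1]
  d$age[d$subject_id == out_id] <- 50
  spec <- match_cost_spec(c("age", "y"))
  flagged <- exclude_hard_to_match(d, spec)
  expect_true(out_id %in% flagged)
  expect_lte(length(flagged), ceiling(0.15 * sum(d$group == "minority")))
})
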