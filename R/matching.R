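#' Specify the matching cost between two subjects
#'
#' The pairing cost is the sum over `variables` of absolute differences,
#' after z-scoring each continuous variable over the union of the two groups
#' (so incommensurate units contribute comparably). Variables listed in
#' `categorical_vars` must agree exactly: any mismatch sets the whole entry
#' to `infeasible_cost`, which [hungarian_match()] treats as unpairable.
#'
#' @param variables Character vector of column names (confounds plus the
#'   target behavior).
#' @param categorical_vars Subset of `variables` requiring exact agreement.
#' @param standardize Z-score continuous variables before differencing.
#' @param infeasible_cost Large finite sentinel for infeasible pairings.
#' @return A `match_cost_spec` object.
#' @export
match_cost_spec <- function(variables, categorical_vars = character(),
                            standardize = TRUE, infeasible_cost = 1e6) {
  if (!is.character(variables) || !length(variables)) {
    abort("`variables` must be a non-empty character vector.")
  }
  if (!all(categorical_vars %in% variables)) {
    abort("`categorical_vars` must be a subset of `variables`.")
  }
  assert_scalar_number(infeasible_cost, "infeasible_cost", 0, strict_lower = TRUE)
  structure(list(variables = variables, categorical_vars = categorical_vars,
                 standardize = isTRUE(standardize),
                 infeasible_cost = infeasible_cost),
            class = "match_cost_spec")
}

#' Pairwise matching cost matrix between two subject sets
#'
#' @param minority,majority Data frames (rows = subjects) holding all
#'   `spec$variables`.
#' @param spec A [match_cost_spec()].
#' @return A `nrow(minority) x nrow(majority)` cost matrix.
#' @export
compute_cost_matrix <- function(minority, majority, spec) {
  stopifnot(inherits(spec, "match_cost_spec"))
  if (!nrow(minority) || !nrow(majority)) abort("Both subject sets must be non-empty.")
  for (v in spec$variables) {
    if (is.null(minority[[v]]) || is.null(majority[[v]])) {
      abort(sprintf("Variable `%s` missing from a subject table.", v))
    }
    if (anyNA(minority[[v]]) || anyNA(majority[[v]])) {
      abort(sprintf("Variable `%s` has missing values.", v))
    }
  }
  cost <- matrix(0, nrow(minority), nrow(majority))
  continuous <- setdiff(spec$variables, spec$categorical_vars)
  for (v in continuous) {
    a <- as.numeric(minority[[v]])
    b <- as.numeric(majority[[v]])
    if (spec$standardize) {
      pool <- c(a, b)
      s <- sd(pool)
      if (s > 0) {
        a <- (a - mean(pool)) / s
        b <- (b - mean(pool)) / s
      }
    }
    cost <- cost + abs(outer(a, b, "-"))
  }
  for (v in spec$categorical_vars) {
    mismatch <- outer(minority[[v]], majority[[v]], "!=")
    cost[mismatch] <- spec$infeasible_cost
  }
  cost
}

#' Iterative within-site matched-pair construction
#'
#' The multisite scheme: within each site, repeatedly (1) Hungarian-match all
#' remaining minority subjects to the site's majority subjects, (2) exclude
#' minority subjects that could not be matched feasibly, (3) exclude the
#' minority member of the single highest-cost pair, then (4) stop when the
#' round limit is reached or the relative decrease in total matching cost
#' from the previous round falls below `rel_tol` (a zero-cost round counts
#' as a zero decrease). The highest-cost drop is applied every round,
#' including the one in which the stopping rule fires, so the returned pairs
#' are the final round's matches minus that round's exclusions.
#'
#' @param data Subject tibble with columns `subject_id`, `group`, `site` and
#'   all `spec$variables`.
#' @param spec A [match_cost_spec()].
#' @param minority_group,majority_group Group labels to pair.
#' @param max_rounds Round limit per site.
#' @param rel_tol Relative cost-decrease stopping threshold.
#' @return A list with `pairs` (tibble: `site`, `minority_id`, `majority_id`,
#'   `cost`), `exclusions` (tibble: `site`, `subject_id`, `reason`, `round`)
#'   and `cost_by_round` (tibble: `site`, `round`, `total_cost`).
#' @export
iterative_site_match <- function(data, spec, minority_group = "minority",
                                 majority_group = "majority",
                                 max_rounds = 100, rel_tol = 0.05) {
  stopifnot(inherits(spec, "match_cost_spec"))
  max_rounds <- assert_count(max_rounds, "max_rounds")
  assert_scalar_number(rel_tol, "rel_tol", 0)
  pairs <- list()
  excl <- list()
  costs <- list()
  for (s in sort(unique(data$site))) {
    dsite <- data[data$site == s, , drop = FALSE]
    mino <- dsite[dsite$group == minority_group, , drop = FALSE]
    majo <- dsite[dsite$group == majority_group, , drop = FALSE]
    if (!nrow(mino) || !nrow(majo)) {
      warn(sprintf("Site `%s` lacks one of the groups; no pairs formed.", s))
      next
    }
    remaining <- mino$subject_id
    prev_cost <- NULL
    for (round in seq_len(max_rounds)) {
      cur <- mino[mino$subject_id %in% remaining, , drop = FALSE]
      if (!nrow(cur)) break
      res <- match_one_site(cur, majo, spec)
      matched <- res$pairs
      match_cost <- sum(matched$cost)
      costs[[length(costs) + 1L]] <- tibble::tibble(
        site = s, round = round, total_cost = match_cost)
      # drop unmatched, then the highest-cost pair's minority member
      dropped <- res$unmatched
      if (length(dropped)) {
        excl[[length(excl) + 1L]] <- tibble::tibble(
          site = s, subject_id = dropped, reason = "unmatched", round = round)
      }
      if (nrow(matched)) {
        worst <- matched$minority_id[which.max(matched$cost)]
        excl[[length(excl) + 1L]] <- tibble::tibble(
          site = s, subject_id = worst, reason = "highest_cost", round = round)
        matched <- matched[matched$minority_id != worst, , drop = FALSE]
        dropped <- c(dropped, worst)
      }
      remaining <- setdiff(remaining, dropped)
      # stopping compares this round's matching cost with the previous
      # round's; a site down to <= 2 pairs stops rather than draining
      stop_now <- round == max_rounds || nrow(matched) <= 2
      if (!is.null(prev_cost)) {
        rel_dec <- if (prev_cost > 0) (prev_cost - match_cost) / prev_cost else 0
        if (rel_dec < rel_tol) stop_now <- TRUE
      }
      if (stop_now) {
        if (nrow(matched)) {
          pairs[[length(pairs) + 1L]] <- tibble::tibble(site = s, matched)
        }
        break
      }
      prev_cost <- match_cost
    }
  }
  list(
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
      tibble::tibble(site = character(), minority_id = character(),
                     majority_id = character(), cost = numeric()),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(site = character(), subject_id = character(),
                     reason = character(), round = integer()),
    cost_by_round = dplyr::bind_rows(costs)
  )
}

# One Hungarian pass for a site; handles more minority than majority by
# solving the transposed problem (the surplus minority are unmatched).
match_one_site <- function(mino, majo, spec) {
  cost <- compute_cost_matrix(mino, majo, spec)
  if (nrow(cost) <= ncol(cost)) {
    res <- hungarian_match(cost, spec$infeasible_cost)
    matched_rows <- which(!is.na(res$assignment))
    pairs <- tibble::tibble(
      minority_id = mino$subject_id[matched_rows],
      majority_id = majo$subject_id[res$assignment[matched_rows]],
      cost = cost[cbind(matched_rows, res$assignment[matched_rows])])
    unmatched <- mino$subject_id[is.na(res$assignment)]
  } else {
    res <- hungarian_match(t(cost), spec$infeasible_cost)
    matched_rows <- which(!is.na(res$assignment))
    pairs <- tibble::tibble(
      minority_id = mino$subject_id[res$assignment[matched_rows]],
      majority_id = majo$subject_id[matched_rows],
      cost = cost[cbind(res$assignment[matched_rows], matched_rows)])
    unmatched <- setdiff(mino$subject_id, pairs$minority_id)
  }
  list(pairs = pairs, unmatched = unmatched)
}

#' Merge sites into folds with balanced matched-pair counts
#'
#' Greedy largest-first bin packing: sites are sorted by matched-pair count
#' (descending, ties broken by site id) and each is assigned whole to the
#' fold with the currently smallest total. Deterministic.
#'
#' @param site_pair_counts Named numeric vector (names = site ids, values =
#'   matched-pair counts) or a data frame with columns `site` and `n_pairs`.
#' @param n_folds Number of folds; must not exceed the number of sites.
#' @return A tibble with columns `site` and `fold`.
#' @export
#' @examples
#' merge_sites_to_folds(c(a = 8, b = 7, c = 5, d = 4, e = 3, f = 3), 3)
merge_sites_to_folds <- function(site_pair_counts, n_folds) {
  if (is.data.frame(site_pair_counts)) {
    counts <- setNames(site_pair_counts$n_pairs, site_pair_counts$site)
  } else {
    counts <- site_pair_counts
  }
  n_folds <- assert_count(n_folds, "n_folds")
  if (length(counts) < n_folds) abort("Fewer sites than folds.")
  ord <- order(-counts, names(counts))
  totals <- numeric(n_folds)
  fold_of <- integer(length(counts))
  for (i in ord) {
    f <- which.min(totals)
    fold_of[i] <- f
    totals[f] <- totals[f] + counts[i]
  }
  tibble::tibble(site = names(counts), fold = fold_of)
}

#' Flag minority subjects that are consistently hard to match
#'
#' For each behavior's cost specification, computes every minority subject's
#' minimal attainable pairing cost against the whole majority pool; a subject
#' is flagged when that minimum exceeds the `pct` quantile of all minimal
#' costs in at least `frac` of the behaviors.
#'
#' @param data Subject tibble.
#' @param specs A single [match_cost_spec()] or a list of them (one per
#'   behavior).
#' @param minority_group,majority_group Group labels.
#' @param pct Quantile defining "high" minimal cost.
#' @param frac Fraction of behaviors in which a subject must be high-cost.
#' @return Character vector of flagged `subject_id`s.
#' @export
exclude_hard_to_match <- function(data, specs, minority_group = "minority",
                                  majority_group = "majority",
                                  pct = 0.9, frac = 0.8) {
  if (inherits(specs, "match_cost_spec")) specs <- list(specs)
  mino <- data[data$group == minority_group, , drop = FALSE]
  majo <- data[data$group == majority_group, , drop = FALSE]
  if (!nrow(mino) || !nrow(majo)) return(character())
  high <- matrix(FALSE, nrow(mino), length(specs))
  for (b in seq_along(specs)) {
    cost <- compute_cost_matrix(mino, majo, specs[[b]])
    mins <- apply(cost, 1, min)
    high[, b] <- mins > stats::quantile(mins, pct)
  }
  mino$subject_id[rowMeans(high) >= frac]
}

#' Construct matched splits for a single-site, family-structured cohort
#'
#' The single-site scheme: after a pre-pass excluding consistently
#' hard-to-match minority subjects ([exclude_hard_to_match()]), each split
#' (1) randomly partitions the remaining minority into `n_folds`
#' family-preserving folds, (2) draws, over `n_iter` random equal-size
#' majority selections (whole families, partitioned to match the minority
#' fold sizes), the Hungarian per-fold matching, keeping the draw that
#' minimizes the maximum per-fold total cost, and (3) distributes the
#' unmatched majority, excluded minority and remaining groups randomly into
#' the folds, families intact. A split is rejected when its best draw still
#' contains an infeasible pair. Splits are accumulated until `n_splits`
#' distinct accepted splits exist; an attempt budget guards termination.
#'
#' @param data Subject tibble with `subject_id`, `group`, `family` and all
#'   `spec$variables`.
#' @param spec A [match_cost_spec()].
#' @param behavior Name of the behavior column (used in error messages).
#' @param n_folds Folds per split.
#' @param n_iter Random majority draws evaluated per split.
#' @param n_splits Accepted splits required.
#' @param seed Integer seed; the whole design is deterministic given it.
#' @param minority_group,majority_group Group labels.
#' @param exclude_hard Run the hard-to-match pre-pass.
#' @param max_attempts Attempt budget across accepted and rejected splits.
#' @return A `matched_design` object: list with `scheme = "hcp_splits"`,
#'   `splits` (each with `pairs` and `fold_of_subject` tibbles),
#'   `excluded_minority_ids`, `n_folds`, `seed`.
#' @export
select_matched_splits_hcp <- function(data, spec, behavior = "y",
                                      n_folds = 10, n_iter = 10000,
                                      n_splits = 40, seed = 1,
                                      minority_group = "minority",
                                      majority_group = "majority",
                                      exclude_hard = TRUE,
                                      max_attempts = max(20, 5 * n_splits)) {
  stopifnot(inherits(spec, "match_cost_spec"))
  n_folds <- assert_count(n_folds, "n_folds")
  n_iter <- assert_count(n_iter, "n_iter")
  n_splits <- assert_count(n_splits, "n_splits")
  excluded <- if (exclude_hard) {
    exclude_hard_to_match(data, spec, minority_group, majority_group)
  } else {
    character()
  }
  mino <- data[data$group == minority_group &
                 !data$subject_id %in% excluded, , drop = FALSE]
  majo <- data[data$group == majority_group, , drop = FALSE]
  rest_ids <- setdiff(data$subject_id, c(mino$subject_id, majo$subject_id))
  if (nrow(mino) < n_folds) abort("Fewer minority subjects than folds.")
  if (nrow(majo) < nrow(mino)) abort("Majority pool smaller than minority pool.")

  splits <- list()
  sub_seeds <- derive_seeds(seed, max_attempts)
  attempt <- 0L
  while (length(splits) < n_splits) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      abort(sprintf(
        "Could not assemble %d matched splits for behavior `%s` within %d attempts.",
        n_splits, behavior, max_attempts))
    }
    split <- with_seed(sub_seeds[attempt],
                       build_one_split(data, mino, majo, rest_ids, spec,
                                       n_folds, n_iter))
    if (!is.null(split)) splits[[length(splits) + 1L]] <- split
  }
  structure(list(scheme = "hcp_splits", splits = splits,
                 excluded_minority_ids = excluded,
                 n_folds = n_folds, seed = seed, behavior = behavior,
                 minority_group = minority_group,
                 majority_group = majority_group),
            class = "matched_design")
}

build_one_split <- function(data, mino, majo, rest_ids, spec, n_folds, n_iter) {
  min_folds <- partition_families(mino$subject_id, mino$family, n_folds)
  fold_sizes <- tabulate(min_folds, n_folds)

  # Quotas per fold and categorical stratum: majority draws must mirror each
  # minority fold's composition on the exact-match variables, otherwise the
  # within-fold assignment is infeasible by construction.
  strata_of <- function(df) {
    if (!length(spec$categorical_vars)) return(rep("all", nrow(df)))
    do.call(paste, c(df[spec$categorical_vars], sep = "\r"))
  }
  mino_strata <- strata_of(mino)
  majo_strata <- strata_of(majo)
  levels_all <- sort(unique(c(mino_strata, majo_strata)))
  need_matrix <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    tabulate(factor(mino_strata[min_folds == f], levels = levels_all),
             length(levels_all))
  }))

  best <- NULL
  for (it in seq_len(n_iter)) {
    draw <- draw_majority_folds(majo, need_matrix, majo_strata, levels_all)
    if (is.null(draw)) next
    fold_pairs <- vector("list", n_folds)
    max_cost <- 0
    feasible <- TRUE
    for (f in seq_len(n_folds)) {
      mf <- mino[min_folds == f, , drop = FALSE]
      wf <- majo[match(draw[[f]], majo$subject_id), , drop = FALSE]
      cost <- compute_cost_matrix(mf, wf, spec)
      res <- hungarian_match(cost, spec$infeasible_cost)
      if (anyNA(res$assignment)) {
        feasible <- FALSE
        break
      }
      fold_pairs[[f]] <- tibble::tibble(
        fold = f, minority_id = mf$subject_id,
        majority_id = wf$subject_id[res$assignment],
        cost = cost[cbind(seq_len(nrow(cost)), res$assignment)])
      max_cost <- max(max_cost, sum(fold_pairs[[f]]$cost))
    }
    if (!feasible) next
    if (is.null(best) || max_cost < best$max_cost) {
      best <- list(max_cost = max_cost, pairs = dplyr::bind_rows(fold_pairs))
    }
  }
  if (is.null(best)) return(NULL)

  fold_of <- setNames(rep(NA_integer_, nrow(data)), data$subject_id)
  fold_of[mino$subject_id] <- min_folds
  fold_of[best$pairs$majority_id] <- best$pairs$fold
  # leftover subjects whose family already has a fold join it; whole
  # remaining families are then distributed randomly — families are never
  # split across folds at any step
  family_of <- setNames(data$family, data$subject_id)
  fam_fold <- tapply(fold_of, family_of, function(f) {
    u <- unique(f[!is.na(f)])
    if (length(u) == 1) u else NA_integer_
  })
  leftover <- names(fold_of)[is.na(fold_of)]
  anchored <- leftover[!is.na(fam_fold[family_of[leftover]])]
  fold_of[anchored] <- fam_fold[family_of[anchored]]
  leftover <- names(fold_of)[is.na(fold_of)]
  if (length(leftover)) {
    lf <- data[match(leftover, data$subject_id), , drop = FALSE]
    fold_of[leftover] <- partition_families(lf$subject_id, lf$family, n_folds)
  }
  list(pairs = best$pairs,
       fold_of_subject = tibble::tibble(subject_id = names(fold_of),
                                        fold = unname(fold_of)),
       max_fold_cost = best$max_cost)
}

# Randomly assign whole families to folds, balancing fold sizes: shuffle
# families, then give each to the currently smallest fold.
partition_families <- function(ids, families, n_folds) {
  fams <- split(seq_along(ids), families)
  fams <- fams[sample.int(length(fams))]
  sizes <- numeric(n_folds)
  fold <- integer(length(ids))
  for (members in fams) {
    f <- which.min(sizes)
    fold[members] <- f
    sizes[f] <- sizes[f] + length(members)
  }
  fold
}

# Draw whole majority families to fill per-fold, per-stratum quotas exactly;
# returns NULL when the shuffled family stream cannot fill them.
draw_majority_folds <- function(majo, need_matrix, majo_strata, levels_all) {
  idx_by_fam <- split(seq_len(nrow(majo)), majo$family)
  idx_by_fam <- idx_by_fam[sample.int(length(idx_by_fam))]
  need <- need_matrix
  n_folds <- nrow(need)
  out <- replicate(n_folds, character(), simplify = FALSE)
  for (members in idx_by_fam) {
    cnt <- tabulate(factor(majo_strata[members], levels = levels_all),
                    length(levels_all))
    fits <- which(vapply(seq_len(n_folds),
                         function(f) all(need[f, ] >= cnt), logical(1)))
    if (!length(fits)) next
    f <- fits[which.max(rowSums(need)[fits])]
    out[[f]] <- c(out[[f]], majo$subject_id[members])
    need[f, ] <- need[f, ] - cnt
    if (all(need == 0)) return(out)
  }
  NULL
}

#' Construct a matched multisite design with site-merged folds
#'
#' Runs [iterative_site_match()] within each site, merges sites into
#' `n_folds` folds with [merge_sites_to_folds()], and assigns every subject
#' (matched or not) to the fold of their site; families share sites, so the
#' family co-fold constraint is automatic.
#'
#' @inheritParams iterative_site_match
#' @param behavior Behavior column name recorded in the design.
#' @param n_folds Number of folds to merge the sites into.
#' @return A `matched_design` with `scheme = "abcd_sites"` and one split.
#' @export
select_matched_design_abcd <- function(data, spec, behavior = "y",
                                       n_folds = 10,
                                       minority_group = "minority",
                                       majority_group = "majority",
                                       max_rounds = 100, rel_tol = 0.05) {
  sm <- iterative_site_match(data, spec, minority_group, majority_group,
                             max_rounds, rel_tol)
  counts <- dplyr::count(sm$pairs, .data$site, name = "n_pairs")
  all_sites <- sort(unique(data$site))
  counts <- dplyr::left_join(tibble::tibble(site = all_sites), counts,
                             by = "site")
  counts$n_pairs[is.na(counts$n_pairs)] <- 0L
  fold_map <- merge_sites_to_folds(counts, n_folds)
  pairs <- dplyr::left_join(sm$pairs, fold_map, by = "site")
  fold_of <- dplyr::left_join(
    tibble::tibble(subject_id = data$subject_id, site = data$site),
    fold_map, by = "site")[, c("subject_id", "fold")]
  structure(list(scheme = "abcd_sites",
                 splits = list(list(pairs = pairs, fold_of_subject = fold_of)),
                 site_match = sm, site_folds = fold_map,
                 excluded_minority_ids = unique(sm$exclusions$subject_id),
                 n_folds = n_folds, seed = NULL, behavior = behavior,
                 minority_group = minority_group,
                 majority_group = majority_group),
            class = "matched_design")
}

#' @export
print.matched_design <- function(x, ...) {
  np <- vapply(x$splits, function(s) nrow(s$pairs), integer(1))
  cat(sprintf("<matched_design> scheme %s: %d split(s), %d fold(s), %s pairs/split\n",
              x$scheme, length(x$splits), x$n_folds,
              paste(range(np), collapse = "-")))
  if (length(x$excluded_minority_ids)) {
    cat(sprintf("  %d minority subject(s) excluded\n",
                length(x$excluded_minority_ids)))
  }
  invisible(x)
}

#' Validate matched pairs with paired t tests
#'
#' For every split and variable, a paired t test on the minority-minus-
#' majority differences, with Benjamini-Hochberg correction across the whole
#' family of tests (all variables x all splits). Zero-variance differences
#' yield `t = 0`, `p = 1` with a warning.
#'
#' @param data Subject tibble.
#' @param design A `matched_design`.
#' @param variables Columns to test (confounds plus behaviors).
#' @param q FDR level.
#' @return A tibble: `split`, `variable`, `mean_difference`, `statistic`,
#'   `p_value`, `p_adjusted`, `rejected`.
#' @export
validate_matching <- function(data, design, variables, q = 0.05) {
  stopifnot(inherits(design, "matched_design"))
  rows <- list()
  for (s in seq_along(design$splits)) {
    pairs <- design$splits[[s]]$pairs
    if (nrow(pairs) < 2) abort("Need at least 2 pairs per split.")
    a <- data[match(pairs$minority_id, data$subject_id), , drop = FALSE]
    b <- data[match(pairs$majority_id, data$subject_id), , drop = FALSE]
    for (v in variables) {
      d <- as.numeric(a[[v]]) - as.numeric(b[[v]])
      if (sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
        if (any(d != 0)) {
          warn(sprintf("Constant nonzero differences for `%s`; t reported as 0.", v))
        }
        tt <- list(statistic = 0, p.value = 1)
      } else {
        ht <- t.test(d)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        split = s, variable = v, mean_difference = mean(d),
        statistic = tt$statistic, p_value = tt$p.value)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$rejected <- out$p_adjusted <= q
  out
}
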