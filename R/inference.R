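#' Multilevel block permutation test of predictability
#'
#' Tests whether predictions carry signal by permuting the predicted scores
#' under exchangeability blocks: whole blocks are permuted only among blocks
#' of the same size, and orderings are shuffled within blocks, so dependent
#' observations (e.g. family members) move together. The p-value uses the
#' add-one estimator `p = (1 + #{null >= observed}) / (1 + n_perm)` for the
#' one-sided (greater) accuracy statistic, so it is never exactly 0.
#'
#' @param y_true,y_pred Test-set vectors.
#' @param blocks Block labels (e.g. family ids) covering all subjects;
#'   all-singleton blocks reduce to an ordinary permutation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param statistic `"pearson"` or a function `f(y_true, y_pred)` returning
#'   a scalar accuracy.
#' @param strata Optional outer stratification labels (must be constant
#'   within each block): blocks are then permuted only among same-size
#'   blocks of the same stratum. Use this to keep cross-validated
#'   predictions within their own train/test division, whose model offsets
#'   are not exchangeable across divisions.
#' @return A `permutation_result`: `observed`, `null_values`, `p`, `n_perm`,
#'   `seed`.
#' @export
block_permutation_predictability <- function(y_true, y_pred, blocks,
                                             n_perm = 1000, seed = 1,
                                             statistic = "pearson",
                                             strata = NULL) {
  n_perm <- assert_count(n_perm, "n_perm")
  if (length(blocks) != length(y_true) || length(y_true) != length(y_pred)) {
    abort("`y_true`, `y_pred` and `blocks` must have equal length.")
  }
  stat_fn <- if (is.function(statistic)) statistic else
    function(y, yhat) cor(y, yhat)
  observed <- stat_fn(y_true, y_pred)
  if (!is.null(strata)) {
    if (length(strata) != length(blocks)) {
      abort("`strata` must have the same length as `blocks`.")
    }
    strata <- as.character(strata)
    if (any(tapply(strata, blocks, function(v) length(unique(v))) > 1)) {
      abort("Each block must lie within a single stratum.")
    }
    blocks <- paste(strata, blocks, sep = "\r")
    members <- split(seq_along(blocks), blocks)
    key <- paste(vapply(members, function(ix) strata[ix[1]], character(1)),
                 lengths(members))
    by_size <- split(members, key)
  } else {
    members <- split(seq_along(blocks), blocks)
    by_size <- split(members, lengths(members))
  }
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_fn(y_true, y_pred[block_permute_indices_fast(by_size,
                                                        length(blocks))])
    }, numeric(1))
  })
  new_permutation_result(observed, null_values, n_perm, seed,
                         alternative = "greater",
                         statistic_name = if (is.function(statistic))
                           "custom" else statistic)
}

# One block-respecting permutation of indices: blocks swap only with
# same-size blocks; orderings shuffle within each block.
block_permute_indices <- function(blocks) {
  members <- split(seq_along(blocks), blocks)
  by_size <- split(members, lengths(members))
  block_permute_indices_fast(by_size, length(blocks))
}

# Precomputed-structure version used inside the permutation loop:
# `by_size` maps block size -> list of index vectors of that size.
block_permute_indices_fast <- function(by_size, n) {
  out <- integer(n)
  for (same in by_size) {
    s <- length(same[[1]])
    src <- unlist(same, use.names = FALSE)
    perm <- sample.int(length(same))
    dst <- unlist(same[perm], use.names = FALSE)
    if (s > 1) {
      dst <- unlist(lapply(split(dst, rep(seq_along(same), each = s)),
                           function(v) v[sample.int(s)]),
                    use.names = FALSE)
    }
    out[src] <- dst
  }
  out
}

#' Flip-label permutation test for a group accuracy difference
#'
#' Observed statistic: `metric(group a) - metric(group b)` over matched test
#' pairs. The null distribution rebuilds the statistic after shuffling the
#' group labels. Two shuffles are offered. The default (`pairwise = FALSE`)
#' permutes the labels globally across all `2 m` pair members (within
#' `strata` when given), relying on the matched design having equalized the
#' two groups. `pairwise = TRUE` instead swaps the labels within each
#' matched pair independently with probability 1/2; this preserves the
#' pairing but is anticonservative when the pairing itself was chosen by
#' similarity matching — the assignment step makes pair members
#' non-exchangeable (most visibly with small candidate pools), which is why
#' it is not the default. Two-sided p by symmetric tail counting with the
#' add-one estimator.
#'
#' @param pairs A tibble with columns `y_true_a`, `y_pred_a`, `y_true_b`,
#'   `y_pred_b`: one row per matched pair (a = first group, b = second).
#' @param metric_fn Function `f(y_true, y_pred)` returning a scalar group
#'   metric (e.g. a closure around [predictive_cod()] with a fixed SST).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param pairwise Swap labels within pairs instead of globally (see above).
#' @param strata Optional per-pair stratification labels for the global
#'   shuffle (e.g. the train/test division each pair was predicted in);
#'   labels are then permuted within pairs of the same stratum only.
#' @return A `permutation_result` with `alternative = "two.sided"`.
#' @export
flip_label_test <- function(pairs, metric_fn, n_perm = 1000, seed = 1,
                            pairwise = FALSE, strata = NULL) {
  n_perm <- assert_count(n_perm, "n_perm")
  need <- c("y_true_a", "y_pred_a", "y_true_b", "y_pred_b")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("`pairs` must have columns %s.", paste(need, collapse = ", ")))
  }
  m <- nrow(pairs)
  if (m < 2) abort("Need at least 2 matched pairs.")
  ya <- pairs$y_true_a; pa <- pairs$y_pred_a
  yb <- pairs$y_true_b; pb <- pairs$y_pred_b
  observed <- metric_fn(ya, pa) - metric_fn(yb, pb)
  if (!is.null(strata) && length(strata) != m) {
    abort("`strata` must have one label per pair.")
  }
  stratum_of <- if (is.null(strata)) rep(1L, 2L * m) else
    rep(as.integer(factor(strata)), 2L)
  shuffle_within <- split(seq_len(2L * m), stratum_of)
  null_values <- with_seed(seed, {
    all_y <- c(ya, yb)
    all_p <- c(pa, pb)
    vapply(seq_len(n_perm), function(i) {
      if (pairwise) {
        flip <- runif(m) < 0.5
        a_y <- ifelse(flip, yb, ya); a_p <- ifelse(flip, pb, pa)
        b_y <- ifelse(flip, ya, yb); b_p <- ifelse(flip, pa, pb)
      } else {
        lab <- logical(2L * m)
        for (ix in shuffle_within) {
          lab[ix] <- sample(rep(c(TRUE, FALSE), length.out = length(ix)))
        }
        a_y <- all_y[lab]; a_p <- all_p[lab]
        b_y <- all_y[!lab]; b_p <- all_p[!lab]
      }
      metric_fn(a_y, a_p) - metric_fn(b_y, b_p)
    }, numeric(1))
  })
  new_permutation_result(observed, null_values, n_perm, seed,
                         alternative = "two.sided",
                         statistic_name = "group_metric_difference")
}

new_permutation_result <- function(observed, null_values, n_perm, seed,
                                   alternative, statistic_name) {
  p <- switch(alternative,
              greater = (1 + sum(null_values >= observed)) / (1 + n_perm),
              two.sided = (1 + sum(abs(null_values) >= abs(observed))) /
                (1 + n_perm))
  structure(list(observed = observed, null_values = null_values, p = p,
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 statistic_name = statistic_name),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed %.4f, p = %.4g (%s, %d perms)\n",
              x$statistic_name, x$observed, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up false discovery rate control at level `q`.
#'
#' @param p_values Numeric p-values in `(0, 1]`.
#' @param q FDR level.
#' @return Logical rejection flags (empty input gives empty output).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical())
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Classify behaviors as predictable
#'
#' A behavior counts as predictable when (i) its whole-test-set accuracy
#' survives the block permutation test after FDR correction across
#' behaviors, and (ii) its split-averaged accuracy is positive in at least
#' one of the two matched groups. The headline subset additionally requires
#' whole-test-set mean Pearson accuracy strictly above `r_threshold`.
#'
#' @param results Tibble with one row per behavior and columns `behavior`,
#'   `p_perm` (block-permutation p), `mean_acc_minority`,
#'   `mean_acc_majority` (split-averaged group accuracies) and `mean_r`
#'   (whole-test-set Pearson accuracy).
#' @param r_threshold Strict threshold for the headline subset.
#' @param q FDR level across behaviors.
#' @return `results` with added `fdr_pass`, `predictable`, `headline`.
#' @export
classify_predictable <- function(results, r_threshold = 0.15, q = 0.05) {
  need <- c("behavior", "p_perm", "mean_acc_minority", "mean_acc_majority",
            "mean_r")
  if (!all(need %in% names(results))) {
    abort(sprintf("`results` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  results$fdr_pass <- fdr_bh(results$p_perm, q)
  results$predictable <- results$fdr_pass &
    (results$mean_acc_minority > 0 | results$mean_acc_majority > 0)
  results$headline <- results$predictable & results$mean_r > r_threshold
  results
}
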