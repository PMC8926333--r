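#' Pooled training variance (SST)
#'
#' Population-denominator variance of the pooled matched training scores of
#' both compared groups: `sum((y_j - mean(y))^2) / N`. It is shared across
#' the groups being compared — the total variance is deliberately not
#' group-specific, so group differences in predictive COD reflect error,
#' not a group-specific yardstick.
#'
#' @param y_train Pooled matched training scores.
#' @return The SST (a scalar, `> 0`).
#' @export
training_sst <- function(y_train) {
  if (length(y_train) < 2) abort("Need at least 2 training subjects.")
  sst <- pop_var(y_train)
  if (sst == 0) abort("Constant training scores: SST is 0 and COD undefined.")
  sst
}

#' Predictive coefficient of determination
#'
#' `1 - SSE_group / SST`, with `SSE_group = mean((y - yhat)^2)` over the
#' group's test subjects and `SST` the pooled training variance from
#' [training_sst()]. Unlike correlation, this metric is sensitive to both
#' scale and systematic shifts of the predictions, and can be negative.
#'
#' @param y_true,y_pred Equal-length test vectors.
#' @param sst Pooled training variance, `> 0`.
#' @return The predictive COD (`<= 1`, possibly negative).
#' @export
predictive_cod <- function(y_true, y_pred, sst) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (!length(y_true)) abort("Empty input.")
  assert_scalar_number(sst, "sst", 0, strict_lower = TRUE)
  1 - mean((y_true - y_pred)^2) / sst
}

#' Pearson prediction accuracy
#'
#' Sample correlation between true and predicted scores. Invariant to
#' positive affine transforms of the predictions — which is exactly why it
#' can disagree with predictive COD when predictions are systematically
#' shifted for one group. Constant inputs yield `NA` with a warning.
#'
#' @param y_true,y_pred Equal-length vectors, `n >= 3`.
#' @return Pearson r, or `NA` when undefined.
#' @export
pearson_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (length(y_true) < 3) abort("Need n >= 3.")
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    warn("Constant vector: Pearson accuracy undefined; returning NA.")
    return(NA_real_)
  }
  cor(y_true, y_pred)
}

#' Prediction shift
#'
#' The square of the mean signed difference between predicted and true
#' scores — a systematic over/under-prediction measure that correlation
#' cannot see.
#'
#' @param y_true,y_pred Equal-length vectors.
#' @return `(mean(y_pred - y_true))^2`.
#' @export
prediction_shift <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (!length(y_true)) abort("Empty input.")
  mean(y_pred - y_true)^2
}

#' Levene's test for equality of variances (two groups)
#'
#' Classic mean-centered Levene: one-way ANOVA on the absolute deviations
#' from each group's mean, with p from the F distribution. When the
#' within-group deviations are exactly constant but group levels differ, the
#' statistic diverges and the test reports `W = Inf`, `p = 0`; when both
#' numerator and denominator vanish, `W = 0`, `p = 1`.
#'
#' @param y_a,y_b Numeric vectors, each of length `>= 2`.
#' @return A list with `statistic` (W) and `p_value`.
#' @export
levene_test <- function(y_a, y_b) {
  if (length(y_a) < 2 || length(y_b) < 2) abort("Each group needs n >= 2.")
  z <- c(abs(y_a - mean(y_a)), abs(y_b - mean(y_b)))
  g <- rep(1:2, c(length(y_a), length(y_b)))
  n <- length(z)
  k <- 2L
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[g])^2) / (n - k)
  if (den == 0) {
    if (num == 0) return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf, p_value = 0))
  }
  W <- num / den
  list(statistic = W, p_value = pf(W, k - 1, n - k, lower.tail = FALSE))
}

#' Group-wise accuracy summaries of a prediction result
#'
#' For each train/test division and each matched group, computes the
#' group's mean squared error, predictive COD (against the division's
#' pooled matched-training SST), Pearson accuracy, prediction shift and
#' behavioral variance over the matched test-pair members of that group.
#' For the single-cohort scheme the per-fold values are then averaged
#' across the folds of each split (one value per split); for the multisite
#' scheme each of the `choose(10, 3)` divisions is reported directly,
#' never averaged.
#'
#' @param result A [run_prediction()] result.
#' @param sst_policy `"matched"` (pooled matched training pairs, the
#'   default) or `"all"` (the whole training set).
#' @param by_division Return per-division rows without the single-cohort
#'   fold averaging.
#' @return A `group_accuracy` tibble: `split`, `group`, `n`, `sse`, `sst`,
#'   `predictive_cod`, `pearson_r`, `prediction_shift`,
#'   `behavioral_variance`.
#' @export
summarize_groups <- function(result, sst_policy = c("matched", "all"),
                             by_division = FALSE) {
  stopifnot(inherits(result, "prediction_result"))
  sst_policy <- match.arg(sst_policy)
  sst_col <- if (sst_policy == "matched") "sst_matched" else "sst_all"
  preds <- result$predictions
  preds <- preds[!is.na(preds$pair_id), , drop = FALSE]
  divs <- result$divisions

  per_div <- preds |>
    dplyr::group_by(.data$division, .data$split, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      sse = mean((.data$y_true - .data$y_pred)^2),
      pearson_r = if (dplyr::n() >= 3 && sd(.data$y_true) > 0 &&
                        sd(.data$y_pred) > 0)
        cor(.data$y_true, .data$y_pred) else NA_real_,
      prediction_shift = mean(.data$y_pred - .data$y_true)^2,
      behavioral_variance = pop_var(.data$y_true),
      .groups = "drop") |>
    dplyr::left_join(divs[, c("division", sst_col)], by = "division") |>
    dplyr::rename(sst = dplyr::all_of(sst_col)) |>
    dplyr::mutate(predictive_cod = 1 - .data$sse / .data$sst)

  if (by_division || result$scheme == "abcd_sites") {
    out <- dplyr::select(per_div, dplyr::all_of(c(
      "division", "split", "group", "n", "sse", "sst", "predictive_cod",
      "pearson_r", "prediction_shift", "behavioral_variance")))
    if (result$scheme == "abcd_sites" && !by_division) {
      out$split <- out$division  # each held-out triple is its own split
    }
  } else {
    out <- per_div |>
      dplyr::group_by(.data$split, .data$group) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(
        "n", "sse", "sst", "predictive_cod", "pearson_r",
        "prediction_shift", "behavioral_variance")),
        ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  }
  class(out) <- c("group_accuracy", class(out))
  out
}
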