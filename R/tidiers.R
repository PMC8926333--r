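# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted kernel ridge model
#'
#' @param x A `krr_model`.
#' @param ... Unused.
#' @return One row per training subject with its dual coefficient.
#' @method tidy krr_model
#' @export
tidy.krr_model <- function(x, ...) {
  tibble::tibble(subject = seq_len(x$n_train),
                 dual_coefficient = x$dual_coefficients)
}

#' @rdname tidy.krr_model
#' @method glance krr_model
#' @export
glance.krr_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_train = x$n_train)
}

#' Tidy a fitted linear ridge model
#'
#' @param x A `linear_ridge_model`.
#' @param ... Unused.
#' @return One row per edge with its primal coefficient.
#' @method tidy linear_ridge_model
#' @export
tidy.linear_ridge_model <- function(x, ...) {
  tibble::tibble(edge = seq_along(x$coefficients),
                 estimate = x$coefficients)
}

#' @rdname tidy.linear_ridge_model
#' @method glance linear_ridge_model
#' @export
glance.linear_ridge_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_train = x$n_train)
}

#' Tidy a permutation test result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value and
#'   permutation settings.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_name, observed = x$observed,
                 p_value = x$p, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p, n_perm = x$n_perm,
                 null_mean = mean(x$null_values),
                 null_sd = sd(x$null_values))
}

#' Tidy a matched design
#'
#' @param x A `matched_design`.
#' @param ... Unused.
#' @return One row per matched pair per split: `split`, `fold`,
#'   `minority_id`, `majority_id`, `cost`.
#' @method tidy matched_design
#' @export
tidy.matched_design <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$splits), function(s) {
    tibble::tibble(split = s, x$splits[[s]]$pairs)
  }))
}

#' @rdname tidy.matched_design
#' @method glance matched_design
#' @export
glance.matched_design <- function(x, ...) {
  np <- vapply(x$splits, function(s) nrow(s$pairs), integer(1))
  tibble::tibble(scheme = x$scheme, n_splits = length(x$splits),
                 n_folds = x$n_folds, n_pairs_min = min(np),
                 n_pairs_max = max(np),
                 n_excluded = length(x$excluded_minority_ids))
}

#' Tidy a prediction result
#'
#' @param x A `prediction_result`.
#' @param ... Unused.
#' @return The per-subject, per-division prediction table.
#' @method tidy prediction_result
#' @export
tidy.prediction_result <- function(x, ...) x$predictions

#' @rdname tidy.prediction_result
#' @method glance prediction_result
#' @export
glance.prediction_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, model_type = x$model_type,
                 training_arm = x$training_arm,
                 n_divisions = nrow(x$divisions),
                 n_predictions = nrow(x$predictions),
                 mean_lambda = mean(x$divisions$lambda))
}

#' Tidy an experiment result
#'
#' @param x A `fairness_experiment`.
#' @param ... Unused.
#' @return The per-behavior inference table.
#' @method tidy fairness_experiment
#' @export
tidy.fairness_experiment <- function(x, ...) x$behaviors

#' @rdname tidy.fairness_experiment
#' @method glance fairness_experiment
#' @export
glance.fairness_experiment <- function(x, ...) {
  tibble::tibble(scheme = x$config$scheme, model_type = x$config$model_type,
                 training_arm = x$config$training_arm,
                 n_behaviors = nrow(x$behaviors),
                 n_predictable = sum(x$behaviors$predictable),
                 n_headline = sum(x$behaviors$headline),
                 relation_r = if (is.null(x$relation)) NA_real_ else
                   x$relation$estimate)
}
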