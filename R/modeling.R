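#' Fit a confound-regression model on training subjects
#'
#' Ordinary least squares (with intercept) of the behavioral score and of
#' every FC edge on the confound matrix, estimated on training subjects
#' only. The fitted model is later applied to held-out subjects with
#' [apply_confound_model()]; fitting on the training side only avoids
#' leaking test information through whole-sample residualization.
#'
#' @param data Training tibble with the behavior column, the matrix column
#'   `fc` and all confound columns.
#' @param confounds Character vector of confound column names.
#' @param behavior Behavior column name.
#' @return A `confound_model` with the per-target coefficients.
#' @export
fit_confound_model <- function(data, confounds, behavior = "y") {
  n <- nrow(data)
  if (n < length(confounds) + 2) {
    abort("Need at least n_confounds + 2 training subjects.")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, confounds, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Rank-deficient confound matrix; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  Y <- cbind(data[[behavior]], data$fc)
  B <- qr.coef(qrX, Y)
  structure(list(confounds = confounds, behavior = behavior,
                 beta_y = B[, 1], beta_fc = B[, -1, drop = FALSE]),
            class = "confound_model")
}

#' Residualize behavior and FC with a fitted confound model
#'
#' Subtracts the training-estimated confound fits from the supplied data;
#' applied to the training set itself, the residuals are exactly orthogonal
#' to the confounds.
#'
#' @param model A [fit_confound_model()] result.
#' @param data Tibble with the same behavior, confound and `fc` columns.
#' @return `data` with the behavior column and `fc` replaced by residuals.
#' @export
apply_confound_model <- function(model, data) {
  stopifnot(inherits(model, "confound_model"))
  if (!all(model$confounds %in% names(data))) {
    abort("Confound columns missing from `data`.")
  }
  X <- cbind(1, as.matrix(data[, model$confounds, drop = FALSE]))
  data[[model$behavior]] <- data[[model$behavior]] - drop(X %*% model$beta_y)
  data$fc <- data$fc - X %*% model$beta_fc
  data
}

#' Pearson-correlation kernel between FC vectors
#'
#' Entry `(s, i)` is the Pearson correlation between row `s` of `fc_a` and
#' row `i` of `fc_b` — the similarity function of the kernel regression:
#' subjects with more similar connectomes get more similar predictions.
#'
#' @param fc_a,fc_b Subject x edge matrices with matching edge counts.
#' @return A `nrow(fc_a) x nrow(fc_b)` kernel matrix.
#' @export
correlation_kernel <- function(fc_a, fc_b = fc_a) {
  fc_a <- as.matrix(fc_a)
  fc_b <- as.matrix(fc_b)
  if (ncol(fc_a) != ncol(fc_b)) abort("Edge counts differ.")
  if (ncol(fc_a) < 2) abort("Need at least 2 edges.")
  check_rows <- function(m) {
    v <- apply(m, 1, function(r) max(r) - min(r))
    if (any(v == 0)) abort("Zero-variance FC row(s); cannot correlate.")
  }
  check_rows(fc_a)
  check_rows(fc_b)
  cor(t(fc_a), t(fc_b))
}

#' Fit kernel ridge regression
#'
#' Solves `(K + lambda I) alpha = y` for the dual coefficients, so a test
#' subject's prediction is the similarity-weighted combination
#' `yhat_s = sum_i K(c_s, c_i) alpha_i` of the training scores.
#'
#' @param kernel_train Square symmetric training kernel matrix.
#' @param y_train Training scores.
#' @param lambda Regularization weight, `> 0`.
#' @return A `krr_model` with elements `lambda`, `dual_coefficients`,
#'   `training_y`, `n_train`.
#' @export
fit_krr <- function(kernel_train, y_train, lambda) {
  kernel_train <- as.matrix(kernel_train)
  n <- nrow(kernel_train)
  if (ncol(kernel_train) != n || length(y_train) != n) {
    abort("`kernel_train` must be square and conformable with `y_train`.")
  }
  if (!all(is.finite(kernel_train)) || !all(is.finite(y_train))) {
    abort("Non-finite inputs.")
  }
  assert_scalar_number(lambda, "lambda", 0, strict_lower = TRUE)
  alpha <- drop(solve(kernel_train + diag(lambda, n), y_train))
  structure(list(lambda = lambda, dual_coefficients = alpha,
                 training_y = y_train, n_train = n),
            class = "krr_model")
}

#' Predict from a fitted kernel ridge model
#'
#' @param model A [fit_krr()] result.
#' @param kernel_test_train Test x training kernel matrix.
#' @return Predicted scores `kernel_test_train %*% dual_coefficients`.
#' @export
predict_krr <- function(model, kernel_test_train) {
  stopifnot(inherits(model, "krr_model"))
  kernel_test_train <- matrix(kernel_test_train, ncol = model$n_train)
  drop(kernel_test_train %*% model$dual_coefficients)
}

#' Fit linear ridge regression on edge features
#'
#' Primal solve `(X'X + lambda I) w = X'y`; computed through the dual
#' `w = X'(XX' + lambda I)^{-1} y` when there are more edges than subjects
#' (the two are algebraically identical). Equivalent to kernel ridge with
#' the linear kernel `K = XX'` at matched `lambda`.
#'
#' @param fc_train Training subject x edge matrix.
#' @param y_train Training scores.
#' @param lambda Regularization weight, `> 0`.
#' @return A `linear_ridge_model` with element `coefficients`.
#' @export
fit_linear_ridge <- function(fc_train, y_train, lambda) {
  X <- as.matrix(fc_train)
  if (!all(is.finite(X)) || !all(is.finite(y_train))) abort("Non-finite inputs.")
  assert_scalar_number(lambda, "lambda", 0, strict_lower = TRUE)
  w <- if (ncol(X) > nrow(X)) {
    drop(crossprod(X, solve(tcrossprod(X) + diag(lambda, nrow(X)), y_train)))
  } else {
    drop(solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y_train)))
  }
  structure(list(lambda = lambda, coefficients = w, n_train = nrow(X)),
            class = "linear_ridge_model")
}

#' @rdname fit_linear_ridge
#' @param model A `linear_ridge_model`.
#' @param fc_test Test subject x edge matrix.
#' @export
predict_linear_ridge <- function(model, fc_test) {
  stopifnot(inherits(model, "linear_ridge_model"))
  drop(as.matrix(fc_test) %*% model$coefficients)
}

#' Default regularization grid
#'
#' Fifteen log-spaced values spanning `[1e-3, 1e3]`, scaled by the training
#' size so the grid tracks the magnitude of the kernel's spectrum.
#'
#' @param n_train Training set size.
#' @return Numeric vector of candidate `lambda` values.
#' @export
default_lambda_grid <- function(n_train) {
  10^seq(-3, 3, length.out = 15) * n_train
}

#' Select the ridge penalty by inner cross-validation
#'
#' Grouped k-fold cross-validation inside the training set: grouping units
#' (families or sites) are never split across inner folds. For each
#' candidate `lambda`, inner-validation accuracy (predictive COD by default,
#' with SST from the inner-training scores; optionally Pearson correlation)
#' is averaged over inner folds; the best `lambda` wins, ties going to the
#' smallest. For the kernel model the inner solves reuse one
#' eigendecomposition per inner fold, so the grid adds negligible cost.
#'
#' @param data Training tibble (behavior column + `fc` + grouping column).
#' @param grid Candidate `lambda` values.
#' @param behavior Behavior column name.
#' @param model_type `"kernel"` (correlation kernel) or `"linear"`.
#' @param group_by Column defining inner-fold grouping units.
#' @param inner_folds Number of inner folds.
#' @param metric `"cod"` or `"pearson"`.
#' @param seed Seed for the inner partition.
#' @return A list with `lambda` (the selection) and `score_by_lambda`.
#' @export
nested_cv_select_lambda <- function(data, grid, behavior = "y",
                                    model_type = c("kernel", "linear"),
                                    group_by = "family", inner_folds = 10,
                                    metric = c("cod", "pearson"), seed = 1) {
  model_type <- match.arg(model_type)
  metric <- match.arg(metric)
  if (!length(grid)) abort("`grid` must be non-empty.")
  grid <- sort(grid)
  if (length(grid) == 1) {
    return(list(lambda = grid,
                score_by_lambda = tibble::tibble(lambda = grid,
                                                 score = NA_real_)))
  }
  n <- nrow(data)
  inner_folds <- min(inner_folds, n)
  blocks <- data[[group_by]]
  # grouped inner CV needs at least as many grouping blocks as folds; fall
  # back to finer units (families, then subjects) when sites are too few
  if (length(unique(blocks)) < inner_folds && group_by != "family" &&
      !is.null(data$family)) {
    blocks <- data$family
  }
  if (length(unique(blocks)) < 2) blocks <- data$subject_id
  fold <- with_seed(seed,
                    partition_families(data$subject_id, blocks, inner_folds))
  y <- data[[behavior]]
  K <- if (model_type == "kernel") correlation_kernel(data$fc) else
    tcrossprod(as.matrix(data$fc))
  scores <- matrix(NA_real_, inner_folds, length(grid))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    te <- !tr
    if (!any(te) || sum(tr) < 2) next
    eg <- eigen(K[tr, tr], symmetric = TRUE)
    qty <- crossprod(eg$vectors, y[tr])
    Kte <- K[te, tr, drop = FALSE] %*% eg$vectors
    sst <- pop_var(y[tr])
    for (g in seq_along(grid)) {
      alpha_t <- qty / (eg$values + grid[g])
      pred <- drop(Kte %*% alpha_t)
      scores[f, g] <- if (metric == "cod") {
        1 - mean((y[te] - pred)^2) / sst
      } else if (sd(pred) == 0 || sd(y[te]) == 0) NA_real_ else cor(y[te], pred)
    }
  }
  mean_score <- colMeans(scores, na.rm = TRUE)
  best <- which(mean_score == max(mean_score, na.rm = TRUE))[1]
  list(lambda = grid[best],
       score_by_lambda = tibble::tibble(lambda = grid, score = mean_score))
}

#' Subsample the training population by group composition
#'
#' Builds the three training-composition arms: `minority_only` keeps the
#' training minority, `majority_only` draws per site the same number of
#' majority subjects, and `balanced` keeps both. Within each site the two
#' group counts are equalized: when a site has fewer majority than minority
#' members, minority subjects are randomly dropped to match (and vice
#' versa), so all arms are size-matched site by site.
#'
#' @param data Training tibble with `subject_id`, `group`, `site`.
#' @param mode `"minority_only"`, `"majority_only"` or `"balanced"`.
#' @param minority_group,majority_group Group labels.
#' @param seed Seed for the random draws.
#' @return The selected subset of `data`.
#' @export
subsample_training_population <- function(data, mode = c("minority_only",
                                                         "majority_only",
                                                         "balanced"),
                                          minority_group = "minority",
                                          majority_group = "majority",
                                          seed = 1) {
  mode <- match.arg(mode)
  keep <- with_seed(seed, {
    ids <- character()
    for (s in sort(unique(data$site))) {
      mino <- data$subject_id[data$site == s & data$group == minority_group]
      majo <- data$subject_id[data$site == s & data$group == majority_group]
      k <- min(length(mino), length(majo))
      if (k == 0) {
        warn(sprintf("Site `%s` has no usable %s/%s balance; skipped.", s,
                     minority_group, majority_group))
        next
      }
      mino <- if (length(mino) > k) sample(mino, k) else mino
      majo <- if (length(majo) > k) sample(majo, k) else majo
      ids <- c(ids, switch(mode,
                           minority_only = mino,
                           majority_only = majo,
                           balanced = c(mino, majo)))
    }
    ids
  })
  data[data$subject_id %in% keep, , drop = FALSE]
}

#' Run the full cross-validated prediction over a matched design
#'
#' Orchestrates one behavior end to end. For the single-cohort scheme
#' (`hcp_splits`), every split runs 10-fold cross-validation: per test fold,
#' confounds are fitted on the training folds (policy `"regress"`) and
#' applied to both sides, the ridge penalty is selected by grouped inner
#' cross-validation, the model is fitted and the test fold predicted. For
#' the multisite scheme (`abcd_sites`), all `choose(n_folds, 3)` ways of
#' holding out 3 of the 10 site-merged folds are enumerated as train/test
#' divisions. Training-population arms other than `"full"` subsample the
#' training set with [subsample_training_population()] before fitting.
#'
#' @param data A `synth_dataset` (or compatible tibble with `fc`).
#' @param design A `matched_design` for the same subjects.
#' @param behavior Behavior column name.
#' @param model_type `"kernel"` or `"linear"`.
#' @param confound_policy `"regress"` or `"none"`.
#' @param confounds Confound column names.
#' @param lambda_grid Candidate penalties; defaults to
#'   [default_lambda_grid()] of the training size.
#' @param inner_folds Inner folds for penalty selection.
#' @param training_arm `"full"`, `"minority_only"`, `"majority_only"` or
#'   `"balanced"`.
#' @param seed Master seed for all stochastic steps.
#' @return A `prediction_result`: list with `predictions` (tibble: one row
#'   per test subject per division, with residualized `y_true`, `y_pred`,
#'   `group`, matched-pair id) and `divisions` (tibble: per train/test
#'   division the selected `lambda`, matched-training SST and sizes), plus
#'   metadata.
#' @export
run_prediction <- function(data, design, behavior = "y",
                           model_type = c("kernel", "linear"),
                           confound_policy = c("regress", "none"),
                           confounds = c("age", "motion", "gender"),
                           lambda_grid = NULL, inner_folds = 10,
                           training_arm = "full", seed = 1) {
  model_type <- match.arg(model_type)
  confound_policy <- match.arg(confound_policy)
  stopifnot(inherits(design, "matched_design"))
  training_arm <- match.arg(training_arm,
                            c("full", "minority_only", "majority_only",
                              "balanced"))
  divisions <- enumerate_divisions(design)
  pred_rows <- vector("list", length(divisions))
  div_rows <- vector("list", length(divisions))
  div_seeds <- derive_seeds(seed, length(divisions))
  models <- vector("list", length(divisions))

  for (d in seq_along(divisions)) {
    dv <- divisions[[d]]
    split <- design$splits[[dv$split]]
    fold_of <- setNames(split$fold_of_subject$fold, split$fold_of_subject$subject_id)
    test_ids <- names(fold_of)[fold_of %in% dv$test_folds]
    train_ids <- setdiff(names(fold_of), test_ids)
    train <- data[match(train_ids, data$subject_id), , drop = FALSE]
    test <- data[match(test_ids, data$subject_id), , drop = FALSE]

    if (confound_policy == "regress") {
      cm <- fit_confound_model(train, confounds, behavior)
      train <- apply_confound_model(cm, train)
      test <- apply_confound_model(cm, test)
    }

    # matched-training SST before any arm subsampling (the matched pairs in
    # the training folds define the pooled variance reference)
    pairs <- split$pairs
    train_pair_ids <- c(pairs$minority_id, pairs$majority_id)
    train_pair_ids <- intersect(train_pair_ids, train_ids)
    sst_matched <- pop_var(train[[behavior]][match(train_pair_ids,
                                                   train$subject_id)])

    if (training_arm != "full") {
      train <- subsample_training_population(
        train, training_arm, design$minority_group, design$majority_group,
        seed = div_seeds[d])
    }

    grid <- lambda_grid %||% default_lambda_grid(nrow(train))
    group_col <- if (design$scheme == "abcd_sites") "site" else "family"
    sel <- nested_cv_select_lambda(train, grid, behavior, model_type,
                                   group_by = group_col,
                                   inner_folds = inner_folds,
                                   seed = div_seeds[d])
    if (model_type == "kernel") {
      K <- correlation_kernel(train$fc)
      fit <- fit_krr(K, train[[behavior]], sel$lambda)
      yhat <- predict_krr(fit, correlation_kernel(test$fc, train$fc))
      yhat_train <- predict_krr(fit, K)
    } else {
      fit <- fit_linear_ridge(train$fc, train[[behavior]], sel$lambda)
      yhat <- predict_linear_ridge(fit, test$fc)
      yhat_train <- predict_linear_ridge(fit, train$fc)
    }
    models[[d]] <- list(fit = fit, train_ids = train$subject_id,
                        yhat_train = yhat_train,
                        assoc_learned = pop_cov_vec(train$fc, yhat_train))

    pair_of <- c(setNames(seq_len(nrow(pairs)), pairs$minority_id),
                 setNames(seq_len(nrow(pairs)), pairs$majority_id))
    pred_rows[[d]] <- tibble::tibble(
      division = d, split = dv$split, test_fold_set = dv$label,
      subject_id = test$subject_id, group = test$group,
      family = test$family,
      y_true = test[[behavior]], y_pred = yhat,
      pair_id = unname(pair_of[test$subject_id]))
    div_rows[[d]] <- tibble::tibble(
      division = d, split = dv$split, test_fold_set = dv$label,
      lambda = sel$lambda, sst_matched = sst_matched,
      sst_all = pop_var(train[[behavior]]),
      n_train = nrow(train), n_test = nrow(test))
  }
  structure(list(predictions = dplyr::bind_rows(pred_rows),
                 divisions = dplyr::bind_rows(div_rows),
                 models = models,
                 scheme = design$scheme, behavior = behavior,
                 model_type = model_type, confound_policy = confound_policy,
                 training_arm = training_arm, seed = seed,
                 minority_group = design$minority_group,
                 majority_group = design$majority_group),
            class = "prediction_result")
}

# Train/test divisions implied by a design: one per (split, test fold) for
# the single-cohort scheme; choose(n_folds, 3) held-out triples for the
# site-merged scheme.
enumerate_divisions <- function(design) {
  if (design$scheme == "hcp_splits") {
    out <- list()
    for (s in seq_along(design$splits)) {
      for (f in seq_len(design$n_folds)) {
        out[[length(out) + 1L]] <- list(split = s, test_folds = f,
                                        label = sprintf("s%d_f%d", s, f))
      }
    }
    out
  } else {
    triples <- combn(design$n_folds, 3, simplify = FALSE)
    lapply(seq_along(triples), function(i) {
      list(split = 1L, test_folds = triples[[i]],
           label = paste0("t", paste(triples[[i]], collapse = "_")))
    })
  }
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> %s | %s model | arm %s | %d divisions, %d predictions\n",
    x$scheme, x$model_type, x$training_arm, nrow(x$divisions),
    nrow(x$predictions)))
  invisible(x)
}
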