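#' Configure a reproducible end-to-end audit experiment
#'
#' Bundles every choice of a full audit run: the synthetic cohort (or
#' interchange files), the matching/splitting scheme, the prediction model,
#' confound policy, training-population arm, inference settings and seeds.
#' The defaults describe the desk-scale demonstration: a 40-ROI, ~500
#' subject cohort, 6 behaviors with graded pattern similarity, 3 matched
#' splits and 100 permutations.
#'
#' @param synth A [synth_config()] describing the cohort, or a list with
#'   `subject_path` and `fc_path` naming interchange files.
#' @param pattern_similarities Per-behavior majority/minority pattern
#'   similarities; `NULL` runs the single behavior `y` of `synth`.
#' @param scheme `"hcp"` (single-cohort random splits) or `"abcd"`
#'   (within-site matching, site-merged folds).
#' @param model_type,confound_policy,confounds,training_arm Passed to
#'   [run_prediction()].
#' @param n_folds Folds per split.
#' @param n_splits,n_iter Matched-split settings for the `"hcp"` scheme.
#' @param inner_folds Inner folds for penalty selection.
#' @param lambda_grid Optional explicit penalty grid.
#' @param n_perm Permutations for both inference procedures.
#' @param r_threshold,q Headline accuracy threshold and FDR level.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              pattern_similarities = seq(0.2, 0.95, length.out = 6),
                              scheme = c("hcp", "abcd"),
                              model_type = c("kernel", "linear"),
                              confound_policy = c("regress", "none"),
                              confounds = c("age", "motion", "gender"),
                              training_arm = "full",
                              n_folds = 10, n_splits = 3, n_iter = 30,
                              inner_folds = 5, lambda_grid = NULL,
                              n_perm = 100, r_threshold = 0.15, q = 0.05,
                              seed = 1) {
  scheme <- match.arg(scheme)
  model_type <- match.arg(model_type)
  confound_policy <- match.arg(confound_policy)
  training_arm <- match.arg(training_arm,
                            c("full", "minority_only", "majority_only",
                              "balanced"))
  if (is.list(synth) && !inherits(synth, "synth_config")) {
    if (!file.exists(synth$subject_path) || !file.exists(synth$fc_path)) {
      abort("Interchange files not found.")
    }
  }
  structure(list(synth = synth, pattern_similarities = pattern_similarities,
                 scheme = scheme, model_type = model_type,
                 confound_policy = confound_policy, confounds = confounds,
                 training_arm = training_arm, n_folds = n_folds,
                 n_splits = n_splits, n_iter = n_iter,
                 inner_folds = inner_folds, lambda_grid = lambda_grid,
                 n_perm = n_perm, r_threshold = r_threshold, q = q,
                 seed = assert_count(seed, "seed", min = 0)),
            class = "experiment_config")
}

#' Run a full audit experiment
#'
#' Executes, for every behavior: matched-design construction, cross-
#' validated prediction under the configured training arm, group-wise
#' accuracy summaries, block-permutation predictability and flip-label
#' group-difference inference, and association-pattern recovery; then
#' classifies predictable behaviors, FDR-corrects the difference tests
#' across them, and relates pattern-validity differences to accuracy
#' differences across behaviors. With `out_dir`, all result tables are
#' written as TSV/JSON/YAML together with a manifest of file checksums;
#' rerunning the same configuration reproduces the files byte for byte.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return A `fairness_experiment`: list with `behaviors` (per-behavior
#'   inference/accuracy table), `accuracy` (split-level group accuracies),
#'   `predictions`, `relation` (similarity-accuracy coupling), `config`,
#'   and `manifest` when written to disk.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  data <- experiment_dataset(config)
  behaviors <- attr(data, "behaviors") %||% "y"
  bseeds <- derive_seeds(config$seed + 37L, length(behaviors))

  beh_rows <- list()
  acc_all <- list()
  pred_all <- list()
  assoc_all <- list()
  for (b in seq_along(behaviors)) {
    beh <- behaviors[b]
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("Stage `%s` failed for behavior `%s`: %s",
                      name, beh, conditionMessage(e)))
      })
    }
    spec <- match_cost_spec(c(config$confounds, beh),
                            categorical_vars = "gender")
    design <- stage("matching", {
      if (config$scheme == "hcp") {
        select_matched_splits_hcp(data, spec, behavior = beh,
                                  n_folds = config$n_folds,
                                  n_iter = config$n_iter,
                                  n_splits = config$n_splits,
                                  seed = bseeds[b])
      } else {
        select_matched_design_abcd(data, spec, behavior = beh,
                                   n_folds = config$n_folds)
      }
    })
    pred <- stage("prediction", run_prediction(
      data, design, behavior = beh, model_type = config$model_type,
      confound_policy = config$confound_policy, confounds = config$confounds,
      lambda_grid = config$lambda_grid, inner_folds = config$inner_folds,
      training_arm = config$training_arm, seed = bseeds[b]))
    acc <- stage("evaluation", summarize_groups(pred))
    inf <- stage("inference", behavior_inference(pred, config, bseeds[b]))
    asc <- stage("association", association_analysis(pred, data))

    acc_mino <- mean(acc$predictive_cod[acc$group == pred$minority_group])
    acc_majo <- mean(acc$predictive_cod[acc$group == pred$majority_group])
    beh_rows[[b]] <- tibble::tibble(
      behavior = beh,
      p_perm = inf$predictability$p,
      mean_r = inf$mean_r,
      mean_acc_minority = acc_mino,
      mean_acc_majority = acc_majo,
      diff_observed = inf$difference$observed,
      p_diff = inf$difference$p,
      similarity_minority = asc$similarity_minority,
      similarity_majority = asc$similarity_majority,
      delta_similarity = asc$similarity_majority - asc$similarity_minority,
      delta_accuracy = acc_majo - acc_mino)
    acc_all[[b]] <- tibble::tibble(behavior = beh, acc)
    pred_all[[b]] <- tibble::tibble(behavior = beh, pred$predictions)
    assoc_all[[b]] <- tibble::tibble(
      behavior = beh, edge = asc$learned$edge,
      learned = asc$learned$value,
      true_minority = asc$true_minority$value,
      true_majority = asc$true_majority$value)
  }
  beh_tab <- classify_predictable(dplyr::bind_rows(beh_rows),
                                  r_threshold = config$r_threshold,
                                  q = config$q)
  beh_tab$diff_rejected <- NA
  if (any(beh_tab$predictable)) {
    beh_tab$diff_rejected[beh_tab$predictable] <-
      fdr_bh(beh_tab$p_diff[beh_tab$predictable], config$q)
  }
  relation <- if (nrow(beh_tab) >= 3) {
    similarity_accuracy_relation(beh_tab)
  } else {
    NULL
  }
  accuracy <- dplyr::bind_rows(acc_all)
  class(accuracy) <- c("group_accuracy", class(accuracy))
  out <- structure(list(
    behaviors = beh_tab,
    accuracy = accuracy,
    predictions = dplyr::bind_rows(pred_all),
    association = dplyr::bind_rows(assoc_all),
    relation = relation, config = config), class = "fairness_experiment")
  if (!is.null(out_dir)) out$manifest <- write_experiment(out, data, out_dir)
  out
}

experiment_dataset <- function(config) {
  if (inherits(config$synth, "synth_config")) {
    if (is.null(config$pattern_similarities)) {
      generate_dataset(config$synth)
    } else {
      generate_behavior_suite(config$synth, config$pattern_similarities)
    }
  } else {
    read_dataset_interchange(config$synth$subject_path, config$synth$fc_path)
  }
}

# Whole-test-set predictability (block permutation over families, split 1),
# mean pooled Pearson accuracy across splits, and the matched-pair
# flip-label COD difference test (split 1).
behavior_inference <- function(pred, config, seed) {
  preds <- pred$predictions
  split_r <- vapply(split(preds, preds$split), function(d) {
    cor(d$y_true, d$y_pred)
  }, numeric(1))
  s1 <- preds[preds$split == 1, , drop = FALSE]
  predictability <- block_permutation_predictability(
    s1$y_true, s1$y_pred, blocks = s1$family,
    n_perm = config$n_perm, seed = seed, strata = s1$division)

  pairs1 <- s1[!is.na(s1$pair_id), , drop = FALSE]
  mino <- pairs1[pairs1$group == pred$minority_group, , drop = FALSE]
  majo <- pairs1[pairs1$group == pred$majority_group, , drop = FALSE]
  majo <- majo[match(mino$pair_id, majo$pair_id), , drop = FALSE]
  pair_tab <- tibble::tibble(
    y_true_a = mino$y_true, y_pred_a = mino$y_pred,
    y_true_b = majo$y_true, y_pred_b = majo$y_pred)
  sst1 <- mean(pred$divisions$sst_matched[pred$divisions$split == 1])
  difference <- flip_label_test(
    pair_tab, function(y, yhat) predictive_cod(y, yhat, sst1),
    n_perm = config$n_perm, seed = seed + 1L, strata = mino$division)
  list(predictability = predictability, difference = difference,
       mean_r = mean(split_r))
}

write_experiment <- function(result, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- character()
  p <- function(f) file.path(out_dir, f)
  if (inherits(cfg$synth, "synth_config")) {
    write_synth_config(cfg$synth, p("config.yaml"))
    paths <- c(paths, p("config.yaml"))
  }
  exp_fields <- cfg[setdiff(names(cfg), c("synth", "lambda_grid"))]
  yaml::write_yaml(exp_fields, p("experiment.yaml"))
  write_subject_table(data, p("subjects.tsv"))
  readr::write_tsv(result$behaviors, p("inference.tsv"), progress = FALSE)
  readr::write_tsv(result$accuracy, p("group_accuracy.tsv"), progress = FALSE)
  readr::write_tsv(result$predictions, p("predictions.tsv"), progress = FALSE)
  readr::write_tsv(result$association, p("association_maps.tsv"),
                   progress = FALSE)
  if (!is.null(result$relation)) {
    readr::write_tsv(result$relation$table, p("similarity_accuracy.tsv"),
                     progress = FALSE)
  }
  paths <- c(paths, p("experiment.yaml"), p("subjects.tsv"),
             p("inference.tsv"), p("group_accuracy.tsv"),
             p("predictions.tsv"), p("association_maps.tsv"))
  if (!is.null(result$relation)) paths <- c(paths, p("similarity_accuracy.tsv"))
  sums <- tools::md5sum(sort(paths))
  manifest <- list(package = "fairconn",
                   version = as.character(utils::packageVersion("fairconn")),
                   seed = cfg$seed,
                   files = as.list(setNames(unname(sums), basename(names(sums)))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.fairness_experiment <- function(x, ...) {
  cat(sprintf("<fairness_experiment> %s scheme, %s model, arm %s: %d behavior(s)\n",
              x$config$scheme, x$config$model_type, x$config$training_arm,
              nrow(x$behaviors)))
  cat(sprintf("  predictable: %d; headline (r > %.2f): %d\n",
              sum(x$behaviors$predictable), x$config$r_threshold,
              sum(x$behaviors$headline)))
  if (!is.null(x$relation)) {
    cat(sprintf("  similarity-accuracy coupling r = %.3f\n",
                x$relation$estimate))
  }
  invisible(x)
}

#' Compare training-population arms
#'
#' Tabulates, per behavior and arm, the significant direction of the
#' minority-majority accuracy difference (flip-label test, FDR-corrected
#' within arm across predictable behaviors), and counts behaviors per
#' direction for each arm.
#'
#' @param results Named list of `fairness_experiment` objects sharing the
#'   same dataset configuration, one per training arm.
#' @return A list with `table` (behavior x arm directions) and `counts`
#'   (per arm: `better_minority`, `better_majority`,
#'   `no_significant_difference`).
#' @export
compare_training_arms <- function(results) {
  if (is.null(names(results)) || !length(results)) {
    abort("`results` must be a named list of experiments.")
  }
  seeds <- vapply(results, function(r) {
    if (inherits(r$config$synth, "synth_config")) r$config$synth$seed else NA_integer_
  }, integer(1))
  if (length(unique(seeds)) != 1) {
    abort("Arms were not run on the same dataset configuration.")
  }
  rows <- list()
  for (arm in names(results)) {
    b <- results[[arm]]$behaviors
    direction <- rep("no_significant_difference", nrow(b))
    sig <- !is.na(b$diff_rejected) & b$diff_rejected
    direction[sig & b$diff_observed > 0] <- "better_minority"
    direction[sig & b$diff_observed < 0] <- "better_majority"
    rows[[arm]] <- tibble::tibble(arm = arm, behavior = b$behavior,
                                  diff_observed = b$diff_observed,
                                  p_diff = b$p_diff, direction = direction)
  }
  tab <- dplyr::bind_rows(rows)
  counts <- tab |>
    dplyr::count(.data$arm, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("better_minority", "better_majority",
                "no_significant_difference")) {
    if (is.null(counts[[col]])) counts[[col]] <- 0L
  }
  list(table = tab, counts = counts)
}
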