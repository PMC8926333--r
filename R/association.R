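#' Model-learned brain-behavior association pattern
#'
#' Haufe-style inversion of a predictive model: the importance of each FC
#' edge is the covariance (population denominator, both arguments demeaned)
#' between the training subjects' demeaned edge values and the model's
#' in-sample predictions. Unlike raw model weights, this pattern is
#' interpretable as how each edge covaries with what the model predicts.
#'
#' @param train_fc Training subject x edge matrix.
#' @param y_pred_train In-sample predicted scores of the training subjects.
#' @return An `association_map` tibble with columns `edge` and `value`;
#'   attributes `source = "model_learned"`.
#' @export
model_learned_association <- function(train_fc, y_pred_train) {
  train_fc <- as.matrix(train_fc)
  if (nrow(train_fc) != length(y_pred_train)) abort("Length mismatch.")
  new_association_map(pop_cov_vec(train_fc, y_pred_train),
                      source = "model_learned", group = NA_character_)
}

#' True group-wise brain-behavior association pattern
#'
#' Per-edge covariance between the group's test FC values and the original
#' (not predicted) behavioral scores, computed separately per group.
#'
#' @param fc Group test subject x edge matrix.
#' @param y_true The group's true scores.
#' @param group Optional group label recorded on the map.
#' @return An `association_map` tibble, `source = "true_group"`.
#' @export
true_association <- function(fc, y_true, group = NA_character_) {
  fc <- as.matrix(fc)
  if (!nrow(fc)) abort("Empty group.")
  if (nrow(fc) < 3) abort("Need at least 3 group test subjects.")
  if (nrow(fc) != length(y_true)) abort("Length mismatch.")
  new_association_map(pop_cov_vec(fc, y_true),
                      source = "true_group", group = group)
}

new_association_map <- function(values, source, group) {
  out <- tibble::tibble(edge = seq_along(values), value = as.numeric(values))
  attr(out, "source") <- source
  attr(out, "group") <- group
  class(out) <- c("association_map", class(out))
  out
}

#' Similarity between two association maps
#'
#' Pearson correlation across edges; invariant to positive rescaling of
#' either map. Constant maps yield `NA` with a warning.
#'
#' @param map_a,map_b `association_map` tibbles or plain numeric vectors of
#'   equal length.
#' @return Pearson r, or `NA` when undefined.
#' @export
association_similarity <- function(map_a, map_b) {
  a <- if (is.data.frame(map_a)) map_a$value else as.numeric(map_a)
  b <- if (is.data.frame(map_b)) map_b$value else as.numeric(map_b)
  if (length(a) != length(b)) abort("Maps have different edge counts.")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("Constant association map: similarity undefined; returning NA.")
    return(NA_real_)
  }
  cor(a, b)
}

#' Relate pattern-validity differences to accuracy differences
#'
#' Across behaviors, correlates the group difference in model-pattern
#' validity, `delta_similarity = sim(learned, true_majority) -
#' sim(learned, true_minority)`, with the group accuracy difference,
#' `delta_accuracy = COD_majority - COD_minority` (split-averaged). A
#' positive correlation indicates that behaviors whose learned pattern
#' better resembles one group's true pattern are also predicted more
#' accurately in that group.
#'
#' @param per_behavior Tibble with columns `behavior`, `delta_similarity`,
#'   `delta_accuracy`.
#' @return A list with `estimate` (cross-behavior Pearson r, `NA` when
#'   undefined) and `table` (the scatter table after dropping incomplete
#'   behaviors).
#' @export
similarity_accuracy_relation <- function(per_behavior) {
  need <- c("behavior", "delta_similarity", "delta_accuracy")
  if (!all(need %in% names(per_behavior))) {
    abort(sprintf("`per_behavior` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  ok <- complete.cases(per_behavior[, c("delta_similarity", "delta_accuracy")])
  if (any(!ok)) {
    warn(sprintf("Dropping %d behavior(s) with missing values.", sum(!ok)))
  }
  tab <- per_behavior[ok, , drop = FALSE]
  if (nrow(tab) < 3) abort("Need at least 3 behaviors.")
  est <- if (sd(tab$delta_similarity) == 0 || sd(tab$delta_accuracy) == 0) {
    warn("Constant differences: correlation undefined; returning NA.")
    NA_real_
  } else {
    cor(tab$delta_similarity, tab$delta_accuracy)
  }
  list(estimate = est, table = tab)
}

#' Association maps and pattern validity for a prediction result
#'
#' Aggregates the per-division model-learned association maps of a
#' [run_prediction()] result (averaged across divisions and splits), builds
#' the two group-wise true maps from the matched test-pair members (pooled
#' across divisions), and returns the learned-versus-true similarities.
#'
#' @param result A `prediction_result` (with stored models).
#' @param data The dataset the result was computed on.
#' @return A list with `learned` (association_map), `true_minority`,
#'   `true_majority`, `similarity_minority`, `similarity_majority`.
#' @export
association_analysis <- function(result, data) {
  stopifnot(inherits(result, "prediction_result"))
  maps <- lapply(result$models, function(m) m$assoc_learned)
  learned <- new_association_map(Reduce(`+`, maps) / length(maps),
                                 source = "model_learned",
                                 group = NA_character_)
  preds <- result$predictions
  preds <- preds[!is.na(preds$pair_id), , drop = FALSE]
  true_map <- function(grp) {
    sub <- preds[preds$group == grp, , drop = FALSE]
    fc <- data$fc[match(sub$subject_id, data$subject_id), , drop = FALSE]
    true_association(fc, sub$y_true, group = grp)
  }
  tmin <- true_map(result$minority_group)
  tmaj <- true_map(result$majority_group)
  list(learned = learned, true_minority = tmin, true_majority = tmaj,
       similarity_minority = association_similarity(learned, tmin),
       similarity_majority = association_similarity(learned, tmaj))
}
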