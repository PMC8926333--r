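# Tabular interchange formats: subject table as TSV, FC as a subjects x
# edges TSV with a JSON sidecar fixing the edge ordering, configs as YAML,
# designs as JSON. All writers are deterministic so reruns are byte-identical.

#' Read and write the subject-table / FC interchange format
#'
#' The on-disk interchange for real or synthetic cohorts: a subject TSV
#' (`subject_id`, `group`, `site`, `family`, confounds, behaviors) and an
#' FC matrix TSV (one row per subject, one column per edge) accompanied by a
#' JSON sidecar recording the ROI count and the strictly-lower-triangular
#' column-major edge ordering.
#'
#' @param data A subjects tibble (with matrix column `fc` for the writers).
#' @param path Base path; `write_subject_table()` writes `<path>`,
#'   `write_fc_matrix()` writes `<path>` plus `<path>.json`.
#' @return Readers return tibbles / lists; writers return `path` invisibly.
#' @name interchange
NULL

#' @rdname interchange
#' @export
write_subject_table <- function(data, path) {
  cols <- setdiff(names(data), "fc")
  readr::write_tsv(as.data.frame(data)[, cols, drop = FALSE], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname interchange
#' @export
read_subject_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname interchange
#' @param n_roi ROI count recorded in the sidecar.
#' @export
write_fc_matrix <- function(data, path, n_roi = attr(data, "config")$n_roi) {
  fc <- if (is.matrix(data)) data else data$fc
  ids <- if (is.matrix(data)) rownames(data) %||%
    sprintf("S%04d", seq_len(nrow(data))) else data$subject_id
  df <- as.data.frame(fc)
  names(df) <- sprintf("edge_%d", seq_len(ncol(fc)))
  readr::write_tsv(cbind(data.frame(subject_id = ids), df), path,
                   progress = FALSE)
  sidecar <- list(n_roi = n_roi, n_edges = ncol(fc),
                  edge_order = "strict_lower_triangular_column_major",
                  transform = "fisher_z")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname interchange
#' @export
read_fc_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fc <- as.matrix(tab[, -1, drop = FALSE])
  rownames(fc) <- tab$subject_id
  list(fc = fc, subject_ids = tab$subject_id, n_roi = sidecar$n_roi,
       edge_order = sidecar$edge_order)
}

#' @rdname interchange
#' @param subject_path,fc_path Paths to the two interchange files.
#' @export
read_dataset_interchange <- function(subject_path, fc_path) {
  subjects <- read_subject_table(subject_path)
  fcs <- read_fc_matrix(fc_path)
  ord <- match(subjects$subject_id, fcs$subject_ids)
  if (anyNA(ord)) abort("Subject tables and FC matrix do not align.")
  subjects$fc <- fcs$fc[ord, , drop = FALSE]
  subjects
}

#' Serialize a generator configuration to YAML
#'
#' Only the declarative fields are written; the derived weight vectors and
#' latent structure are reconstructed deterministically from the seed on
#' read, so a round trip reproduces the configuration exactly.
#'
#' @param config A [synth_config()].
#' @param path Output YAML file.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  # doubles are written as 17-significant-digit strings so the round trip
  # is bit-exact (plain YAML floats lose the trailing bits)
  fmt <- function(x) {
    if (is.numeric(x)) as.list(setNames(format(x, digits = 17), names(x)))
    else x
  }
  fields <- config[c("n_majority", "n_minority", "n_other", "n_roi",
                     "n_sites", "pattern_similarity", "noise_sd",
                     "group_mean_shift", "group_variance_ratio",
                     "fc_n_edges", "frames_per_run", "runs_per_subject",
                     "edge_sd", "latent_rank", "latent_share", "seed")]
  fields <- lapply(fields, function(x) format(x, digits = 17))
  fields$family_size_distribution <- fmt(config$family_size_distribution)
  fields$confound_loadings <- lapply(config$confound_loadings, fmt)
  fields$motion_params <- lapply(config$motion_params,
                                 function(x) format(x, digits = 17))
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  f <- yaml::read_yaml(path)
  num <- function(x) {
    v <- unlist(x)
    setNames(as.numeric(v), names(v))
  }
  synth_config(
    n_majority = num(f$n_majority), n_minority = num(f$n_minority),
    n_other = num(f$n_other), n_roi = num(f$n_roi), n_sites = num(f$n_sites),
    family_size_distribution = num(f$family_size_distribution),
    pattern_similarity = num(f$pattern_similarity),
    noise_sd = num(f$noise_sd),
    group_mean_shift = num(f$group_mean_shift),
    group_variance_ratio = num(f$group_variance_ratio),
    confound_loadings = lapply(f$confound_loadings, num),
    fc_n_edges = num(f$fc_n_edges), frames_per_run = num(f$frames_per_run),
    runs_per_subject = num(f$runs_per_subject),
    motion_params = lapply(f$motion_params, function(x) as.numeric(unlist(x))),
    edge_sd = num(f$edge_sd), latent_rank = num(f$latent_rank),
    latent_share = num(f$latent_share), seed = num(f$seed))
}

#' Serialize a matched design to JSON
#'
#' @param design A `matched_design`.
#' @param path Output JSON file.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "matched_design"))
  obj <- list(
    scheme = design$scheme, n_folds = design$n_folds,
    seed = design$seed, behavior = design$behavior,
    excluded_minority_ids = design$excluded_minority_ids,
    splits = lapply(design$splits, function(s) {
      list(pairs = as.data.frame(s$pairs),
           fold_of_subject = as.data.frame(s$fold_of_subject))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write one time-series run as TSV
#'
#' Columns `fd`, `dvars`, then one column per ROI.
#'
#' @param run A `run_timeseries`.
#' @param path Output TSV file.
#' @export
write_run_timeseries <- function(run, path) {
  stopifnot(inherits(run, "run_timeseries"))
  sig <- as.data.frame(run$signal)
  names(sig) <- sprintf("roi_%d", seq_len(ncol(sig)))
  readr::write_tsv(cbind(data.frame(fd = run$fd, dvars = run$dvars), sig),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_run_timeseries
#' @export
read_run_timeseries <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(list(signal = as.matrix(tab[, -(1:2), drop = FALSE]),
                 fd = tab$fd, dvars = tab$dvars),
            class = "run_timeseries")
}
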