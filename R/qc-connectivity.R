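#' Frame-censoring policy
#'
#' Bundles the motion-censoring parameters used throughout quality control:
#' a frame is marked bad when FD or DVARS exceeds its threshold; the bad set
#' is dilated `n_before` frames back and `n_after` frames forward; any
#' surviving uncensored segment shorter than `min_segment` contiguous frames
#' is censored too; and a whole run is discarded when strictly more than
#' `max_censored_fraction` of its frames end up censored.
#'
#' Two presets mirror common adult and developmental processing choices:
#' `censor_policy("hcp")` uses FD > 0.2 mm or DVARS > 75, and
#' `censor_policy("abcd")` uses FD > 0.3 mm or DVARS > 50; both dilate one
#' frame before and two after, require segments of at least five contiguous
#' frames, and discard runs with more than half their frames censored.
#'
#' @param preset Optional `"hcp"` or `"abcd"`; explicit arguments override
#'   preset values.
#' @param fd_threshold FD threshold in mm (`> 0`).
#' @param dvars_threshold DVARS threshold in signal units (`> 0`).
#' @param n_before,n_after Dilation widths in frames (`>= 0`).
#' @param min_segment Minimum surviving contiguous segment length (`>= 1`).
#' @param max_censored_fraction Run-discard threshold in `(0, 1]`; a run is
#'   unusable when its censored fraction strictly exceeds this.
#' @return A `censor_policy` object.
#' @export
#' @examples
#' censor_policy("hcp")
censor_policy <- function(preset = NULL, fd_threshold = NULL,
                          dvars_threshold = NULL, n_before = 1L, n_after = 2L,
                          min_segment = 5L, max_censored_fraction = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("hcp", "abcd"))
    if (is.null(fd_threshold)) fd_threshold <- c(hcp = 0.2, abcd = 0.3)[[preset]]
    if (is.null(dvars_threshold)) dvars_threshold <- c(hcp = 75, abcd = 50)[[preset]]
  }
  assert_scalar_number(fd_threshold, "fd_threshold", 0, strict_lower = TRUE)
  assert_scalar_number(dvars_threshold, "dvars_threshold", 0, strict_lower = TRUE)
  n_before <- assert_count(n_before, "n_before", min = 0)
  n_after <- assert_count(n_after, "n_after", min = 0)
  min_segment <- assert_count(min_segment, "min_segment", min = 1)
  assert_scalar_number(max_censored_fraction, "max_censored_fraction", 0, 1,
                       strict_lower = TRUE)
  structure(list(fd_threshold = fd_threshold, dvars_threshold = dvars_threshold,
                 n_before = n_before, n_after = n_after,
                 min_segment = min_segment,
                 max_censored_fraction = max_censored_fraction),
            class = "censor_policy")
}

#' @export
print.censor_policy <- function(x, ...) {
  cat(sprintf(paste0("<censor_policy> FD > %g mm | DVARS > %g; dilate -%d/+%d; ",
                     "min segment %d; discard run if > %g censored\n"),
              x$fd_threshold, x$dvars_threshold, x$n_before, x$n_after,
              x$min_segment, x$max_censored_fraction))
  invisible(x)
}

#' Root-mean-square differenced signal (DVARS)
#'
#' For frame `i >= 2`, the root mean square over ROIs of the frame-to-frame
#' signal difference: `sqrt(mean((I_i - I_{i-1})^2))`. The differenced
#' quantity has no value at the first frame, which is assigned 0 so that it
#' never triggers censoring by itself.
#'
#' @param signal A frames x ROI numeric matrix.
#' @return A numeric vector of per-frame DVARS values.
#' @export
compute_dvars <- function(signal) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) abort("DVARS needs at least 2 frames.")
  d <- diff(signal)
  c(0, sqrt(rowMeans(d^2)))
}

#' Censor frames by motion criteria
#'
#' Marks frames whose FD or DVARS exceeds the policy thresholds, dilates the
#' marked set (`n_before` back, `n_after` forward), then censors any
#' surviving uncensored segment shorter than `min_segment` contiguous frames.
#' The operation is idempotent. Segments are defined within a run only.
#'
#' @param fd,dvars Equal-length per-frame traces.
#' @param policy A [censor_policy()].
#' @return A logical vector, `TRUE` where the frame is censored.
#' @export
#' @examples
#' fd <- rep(0, 20); fd[8] <- 0.35
#' which(censor_frames(fd, rep(0, 20), censor_policy("hcp")))  # 7:10
censor_frames <- function(fd, dvars, policy) {
  stopifnot(inherits(policy, "censor_policy"))
  if (length(fd) != length(dvars)) abort("`fd` and `dvars` must have equal length.")
  n <- length(fd)
  bad <- fd > policy$fd_threshold | dvars > policy$dvars_threshold
  mask <- bad
  for (i in which(bad)) {
    lo <- max(1L, i - policy$n_before)
    hi <- min(n, i + policy$n_after)
    mask[lo:hi] <- TRUE
  }
  # censor surviving segments shorter than min_segment
  r <- rle(mask)
  short <- !r$values & r$lengths < policy$min_segment
  r$values[short] <- TRUE
  inverse.rle(r)
}

#' Is a run usable after censoring?
#'
#' A run is discarded when strictly more than `max_censored_fraction` of its
#' frames are censored; exactly half censored (under the default 0.5) is
#' still usable.
#'
#' @param mask Logical censoring mask (`TRUE` = censored).
#' @param policy A [censor_policy()].
#' @return `TRUE` if the run is usable.
#' @export
run_usable <- function(mask, policy) {
  stopifnot(inherits(policy, "censor_policy"))
  mean(mask) <= policy$max_censored_fraction
}

#' Compute a Fisher-z RSFC matrix from ROI time series runs
#'
#' Per run, the Pearson correlation matrix is computed over uncensored frames
#' only; correlations are Fisher z-transformed (`atanh`, after clipping to
#' `1 - 1e-7` in magnitude to guard degenerate `r = +/-1`); z-matrices are
#' averaged across usable runs. The diagonal is set to 0.
#'
#' @param runs A list of `run_timeseries` objects (elements `signal`, `fd`,
#'   `dvars`, optional logical `mask`).
#' @param policy Optional [censor_policy()]. When supplied, each run's mask
#'   is (re)computed from its FD/DVARS traces and runs failing
#'   [run_usable()] are dropped. When `NULL`, a run's own `mask` element is
#'   honored if present, otherwise no frame is censored.
#' @param weight_by_frames Average run z-matrices weighted by uncensored
#'   frame count instead of unweighted (default unweighted).
#' @return A symmetric ROI x ROI matrix of averaged Fisher-z correlations
#'   with zero diagonal.
#' @export
compute_rsfc <- function(runs, policy = NULL, weight_by_frames = FALSE) {
  if (!length(runs)) abort("`runs` must be a non-empty list.")
  if (inherits(runs, "run_timeseries")) runs <- list(runs)
  zs <- list()
  wts <- numeric(0)
  for (run in runs) {
    keep <- rep(TRUE, nrow(run$signal))
    if (!is.null(policy)) {
      mask <- censor_frames(run$fd, run$dvars, policy)
      if (!run_usable(mask, policy)) next
      keep <- !mask
    } else if (!is.null(run$mask)) {
      keep <- !run$mask
    }
    if (sum(keep) < 3) {
      abort("A usable run must retain at least 3 uncensored frames.")
    }
    sub <- run$signal[keep, , drop = FALSE]
    sds <- apply(sub, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("Zero-variance ROI(s) in uncensored frames: %s",
                    paste(which(sds == 0), collapse = ", ")))
    }
    r <- cor(sub)
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(r)
    diag(z) <- 0
    zs[[length(zs) + 1L]] <- z
    wts <- c(wts, sum(keep))
  }
  if (!length(zs)) abort("No usable runs after censoring.")
  if (!weight_by_frames) wts <- rep(1, length(zs))
  out <- Reduce(`+`, Map(`*`, zs, wts / sum(wts)))
  diag(out) <- 0
  out
}

#' Vectorize / reconstruct a symmetric RSFC matrix
#'
#' `vectorize_rsfc()` extracts the strictly-lower-triangular entries in
#' column-major order (length `p (p - 1) / 2`); `devectorize_rsfc()` inverts
#' the operation, producing a symmetric matrix with zero diagonal. This edge
#' ordering is the package-wide convention and is recorded in the sidecar of
#' every FC file written by [write_fc_matrix()].
#'
#' @param mat A square symmetric matrix.
#' @return `vectorize_rsfc()`: a numeric edge vector.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[lower.tri(m)] <- 1:3; m <- m + t(m)
#' vectorize_rsfc(m)
vectorize_rsfc <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("`mat` must be square.")
  mat[lower.tri(mat)]
}

#' @rdname vectorize_rsfc
#' @param edges A numeric vector of length `p (p - 1) / 2`.
#' @return `devectorize_rsfc()`: a symmetric `p x p` matrix, zero diagonal.
#' @export
devectorize_rsfc <- function(edges) {
  p <- (1 + sqrt(1 + 8 * length(edges))) / 2
  if (p != round(p)) abort("`edges` length is not p(p-1)/2 for integer p.")
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- edges
  m + t(m)
}
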