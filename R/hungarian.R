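#' Minimum-cost one-to-one assignment (Hungarian matching)
#'
#' Solves the rectangular assignment problem: given a cost matrix with
#' `nrow(cost) <= ncol(cost)`, find the injective row-to-column map
#' minimizing total cost. Implemented as the shortest-augmenting-path
#' (Jonker-Volgenant) variant of the Hungarian algorithm, O(n^2 m).
#'
#' Rows whose assigned cost reaches `infeasible_cost` (the sentinel used by
#' [compute_cost_matrix()] for categorical mismatches) are reported
#' unmatched: their assignment is `NA` and they do not contribute to
#' `total_cost`.
#'
#' @param cost Numeric cost matrix, rows <= columns, all entries finite.
#' @param infeasible_cost Sentinel at or above which a pairing counts as
#'   infeasible; `Inf` (default) disables the check.
#' @return A list with `assignment` (integer vector: column index per row,
#'   `NA` if unmatched), `total_cost` (sum over matched pairs), and
#'   `unmatched_rows`.
#' @export
#' @examples
#' hungarian_match(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))$assignment  # 1, 2
hungarian_match <- function(cost, infeasible_cost = Inf) {
  cost <- as.matrix(cost)
  if (length(cost) == 0) abort("`cost` must be a non-empty matrix.")
  if (!all(is.finite(cost))) abort("`cost` must be finite; use a large sentinel for infeasible pairs.")
  if (nrow(cost) > ncol(cost)) abort("`cost` must have rows <= columns.")
  assignment <- hungarian_solve(cost)
  picked <- cost[cbind(seq_len(nrow(cost)), assignment)]
  bad <- picked >= infeasible_cost
  assignment[bad] <- NA_integer_
  list(assignment = assignment,
       total_cost = sum(picked[!bad]),
       unmatched_rows = which(bad))
}

# Shortest augmenting path with row/column potentials. Column index 1 is the
# virtual start column; real column j lives at j + 1.
hungarian_solve <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)    # row matched to (shifted) column, 0 = none
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      jfree <- which(!used)
      cur <- a[i0, jfree - 1L] - u[i0] - v[jfree]
      upd <- cur < minv[jfree]
      if (any(upd)) {
        minv[jfree[upd]] <- cur[upd]
        way[jfree[upd]] <- j0
      }
      k <- which.min(minv[jfree])
      j1 <- jfree[k]
      delta <- minv[j1]
      uj <- which(used)
      rows <- p[uj]
      u[rows] <- u[rows] + delta
      v[uj] <- v[uj] - delta
      minv[jfree] <- minv[jfree] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_of_col <- p[-1L]
  assignment <- integer(n)
  assignment[match_of_col[match_of_col > 0L]] <- which(match_of_col > 0L)
  assignment
}
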