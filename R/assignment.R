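#' @include utils.R
NULL

#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem minimizing total cost,
#' used by [linkTracks()] to pick the frame-to-frame spot pairing with the
#' smallest total squared displacement. Implementation is the standard
#' O(n^2 m) shortest-augmenting-path Hungarian algorithm with row/column
#' potentials.
#'
#' @param cost numeric matrix of finite costs; if `nrow > ncol` the transposed
#'   problem is solved internally.
#' @return Integer vector of length `nrow(cost)`: `result[i]` is the column
#'   assigned to row `i` (when `nrow <= ncol` every row is assigned; otherwise
#'   unassigned rows are `NA`).
#' @examples
#' solveAssignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3))
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("costs must be finite")
  if (nrow(cost) > ncol(cost)) {
    colOfRow <- solveAssignment(t(cost))
    out <- rep(NA_integer_, nrow(cost))
    out[colOfRow] <- seq_along(colOfRow)
    return(out)
  }
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  ## 1-based port of the potentials formulation; index 1 is the dummy column.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)       # row matched to each column (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used) - 1L          # 0-based column ids incl. dummy
      u[p[usedCols + 1L] + 1L] <- u[p[usedCols + 1L] + 1L] + delta
      v[usedCols + 1L] <- v[usedCols + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
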