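# Minimum-cost bipartite assignment (Hungarian algorithm, shortest
# augmenting path formulation, O(n^3)). Supports rectangular matrices and
# forbidden (gated) pairs marked with Inf: the solver returns the cheapest
# assignment among those of maximal cardinality that avoid forbidden pairs.

# Core solver for a square matrix of finite costs. Returns, for each row,
# the assigned column. Deterministic.
solve_square_lsap <- function(C) {
  n <- nrow(C)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- C[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
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
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign_row[p[j + 1L]] <- j
  assign_row
}

#' Minimum-cost assignment with gating
#'
#' Solves the track-to-detection association problem: given a cost matrix
#' (rows = candidates, columns = detections) with `Inf` marking forbidden
#' (gated) pairs, returns the assignment that, among all maximal matchings
#' avoiding forbidden pairs, minimizes total cost. Rectangular matrices are
#' handled by padding. Ties between equally cheap assignments are broken
#' toward lower row, then lower column indices (via an infinitesimal index
#' bias).
#'
#' @param cost Numeric matrix; entries finite or `Inf` (forbidden).
#' @return A list: `pairs` (two-column matrix of row/column indices, ordered
#'   by row) and `total` (summed cost of the assigned finite entries). An
#'   all-forbidden matrix yields an empty assignment.
#' @export
hungarian <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  empty <- list(pairs = matrix(integer(), 0L, 2L,
                               dimnames = list(NULL, c("row", "col"))),
                total = 0)
  if (nr == 0L || nc == 0L) return(empty)
  if (any(is.na(cost)) || any(cost < Inf & !is.finite(cost)))
    stop("cost entries must be finite or Inf")
  fin <- cost[is.finite(cost)]
  if (length(fin) == 0L) return(empty)
  n <- max(nr, nc)
  # forbidden/padding sentinel: large enough that the solver uses as few
  # sentinel entries as possible (maximal real cardinality), small enough to
  # stay numerically safe
  M <- (sum(abs(fin)) + max(abs(fin)) + 1) * (n + 1)
  C <- matrix(M, n, n)
  C[seq_len(nr), seq_len(nc)] <- ifelse(is.finite(cost), cost, M)
  # near-lexicographic tie-break: negligible bias toward low indices
  eps <- max(1, max(abs(fin))) * 1e-10 / n^2
  bias <- outer(seq_len(n), seq_len(n), function(i, j) (i * n + j) * eps)
  assign_row <- solve_square_lsap(C + bias)
  rows <- seq_len(nr)
  cols <- assign_row[rows]
  ok <- cols <= nc
  ok[ok] <- is.finite(cost[cbind(rows[ok], cols[ok])])
  pairs <- cbind(row = rows[ok], col = cols[ok])
  list(pairs = pairs, total = sum(cost[pairs]))
}
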