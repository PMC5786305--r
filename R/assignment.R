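# Minimum-cost perfect assignment (Hungarian algorithm, potentials
# formulation). Used to match learned topics to planted ones; no linear
# assignment solver ships with the recommended packages, so this is a small
# self-contained O(n^3) implementation.

#' Solve the square linear assignment problem
#'
#' Minimizes `sum_i cost[i, match[i]]` over permutations.
#'
#' @param cost Finite numeric n x n cost matrix.
#' @return Integer vector `match` with `match[i]` the column assigned to
#'   row i.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(1L)
  # column n+1 acts as the virtual "unmatched" column
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials
  p <- integer(n + 1L)   # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) match[p[j]] <- j
  match
}
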