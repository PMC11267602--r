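#' Hungarian (Kuhn-Munkres) assignment
#'
#' Minimum-total-cost perfect matching on a square cost matrix, via the
#' O(n^3) shortest-augmenting-path formulation (Jonker-Volgenant style
#' potentials).  Used to match rotated atoms to target atoms within an
#' equivalence class; no assignment solver is re-exported from elsewhere.
#'
#' @param cost square numeric matrix; `cost[i, j]` = cost of assigning row
#'   `i` to column `j`.
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (n == 0L) return(integer(0))
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)          # row potentials (1-based rows; index n+1 = dummy)
  v <- numeric(n + 1)          # column potentials
  p <- integer(n + 1)          # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i                  # column slot 1 reused as the virtual start
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
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
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}
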