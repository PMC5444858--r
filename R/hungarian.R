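# Minimum-cost bipartite assignment (Hungarian algorithm) for square
# matrices, via row/column potentials and successive shortest augmenting
# paths; O(n^3).  No assignment-solver package is required at run time;
# the test suite cross-checks this implementation against exhaustive
# enumeration.

# a: n x n finite cost matrix; returns integer vector `col` of length n,
# col[i] = column assigned to row i, minimizing the total cost.
lsap_min_square <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(integer(0L))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials; index 1 is the virtual column
  p <- integer(n + 1L)     # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- a[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                     # augment along the alternating path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  col <- integer(n)
  for (j in 2L:(n + 1L)) col[p[j]] <- j - 1L
  col
}
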