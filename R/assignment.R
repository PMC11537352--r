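# Rectangular linear assignment (Hungarian method, shortest augmenting
# path variant with dual potentials), used to map predicted clusters
# onto truth classes by maximum total profile correlation when the
# cluster counts match.

# Minimize sum of cost[i, assignment[i]] over one-to-one assignments.
# Rectangular input is padded square internally; O(n^3).
solve_assignment_min <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  finite <- cost[is.finite(cost)]
  big <- (if (length(finite)) max(abs(finite)) else 1) * n * 10 + 1
  cost[!is.finite(cost)] <- big
  m <- matrix(big, n, n)
  m[seq_len(nr), seq_len(nc)] <- cost
  # column index 1 below is a dummy; real columns are 2..n+1
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials (incl. dummy)
  p <- integer(n + 1)    # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (!used[j]) {
          cur <- m[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
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
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq.int(2L, n + 1L)) if (p[j] > 0L) assign_col[p[j]] <- j - 1L
  assign_col[seq_len(nr)]
}

# Maximize total score; returns, for each row, the assigned column.
solve_assignment_max <- function(score) {
  score <- as.matrix(score)
  finite <- score[is.finite(score)]
  top <- if (length(finite)) max(finite) else 0
  solve_assignment_min(top - score)
}
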