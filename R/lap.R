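## Dense square linear assignment (minimum total cost, one-to-one), used to
## turn each random rotation of the parcel centroids into a true permutation.
## O(n^3) shortest-augmenting-path Hungarian with potentials.

lap_solve <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost),
            all(is.finite(cost)))
  n <- nrow(cost)
  INF <- .Machine$double.xmax
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)     # p[j + 1]: row matched to column j (0 = none)
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
      free_j <- which(!used[-1L])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j + 1L]
        if (any(upd)) {
          minv[free_j[upd] + 1L] <- cur[upd]
          way[free_j[upd] + 1L] <- j0
        }
        k <- which.min(minv[free_j + 1L])
        delta <- minv[free_j[k] + 1L]
        j1 <- free_j[k]
      }
      upd_u <- used
      u[p[upd_u] + 1L] <- u[p[upd_u] + 1L] + delta
      v[upd_u] <- v[upd_u] - delta
      minv[!upd_u] <- minv[!upd_u] - delta
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
  # assignment[i] = column matched to row i
  assignment <- integer(n)
  assignment[p[-1L]] <- seq_len(n)
  assignment
}
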