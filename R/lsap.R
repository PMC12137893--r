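## Exact partial-assignment oracle: square LSAP reduction solved by the
## Jonker-Volgenant shortest-augmenting-path algorithm.

.FORBIDDEN <- 1e8

# Minimum-cost perfect assignment on a square matrix; returns col assigned to
# each row. O(n^3) shortest augmenting paths with dual potentials.
.lsap_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j + 1] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      free_j <- which(!used[2:(n + 1L)])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j + 1L]
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
        k <- which.min(minv[free_j + 1L])
        delta <- minv[free_j[k] + 1L]
        j1 <- free_j[k]
      }
      iu <- which(used)
      u[p[iu] + 1L] <- u[p[iu] + 1L] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
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
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

#' Exact partial assignment with gap states
#'
#' Exact maximizer of the gap-augmented partial assignment objective
#' `sum S_ij X_ij` where every real row and column is matched either to a real
#' partner or to its gap state. Solved by reduction to a square
#' (m+n) x (n+m) assignment: real-real cells carry `S_ij`; row `i` may enter
#' only its own gap slot (scoring its gap-column entry), column `j` likewise;
#' gap-gap cells are free; all other cells are forbidden. Ties are broken
#' toward fewer matched pairs and then lexicographically smallest pair set via
#' an infinitesimal perturbation.
#'
#' @param sim A `similarity_matrix`.
#' @return An `alignment_result` (direction `"row"`) with
#'   `total_similarity` = interior similarity over the pairs and attribute
#'   `"objective"` = full objective including gap scores.
#' @export
exact_plsap <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  m <- sim$m
  n <- sim$n
  S <- sim$S
  N <- m + n
  W <- matrix(-.FORBIDDEN, N, N)
  # layout: rows = [query 1..m, gap clones of target cols 1..n]
  #         cols = [target 1..n, gap clones of query rows 1..m]
  W[seq_len(m), seq_len(n)] <- S[seq_len(m), seq_len(n)]
  for (i in seq_len(m)) W[i, n + i] <- S[i, n + 1L]
  for (j in seq_len(n)) W[m + j, j] <- S[m + 1L, j]
  W[m + seq_len(n), n + seq_len(m)] <- 0

  # tie-break perturbation: prefer gaps (fewer pairs), then smaller (i, j)
  scale <- max(1, max(abs(S)))
  eps1 <- 1e-7 * scale
  eps2 <- eps1 * 1e-3
  idx <- outer(seq_len(m), seq_len(n), function(i, j) ((i - 1) * n + j))
  W[seq_len(m), seq_len(n)] <- W[seq_len(m), seq_len(n)] -
    eps1 - eps2 * idx / (m * n)

  cost <- max(W[W > -.FORBIDDEN]) - W
  cost[W <= -.FORBIDDEN] <- .FORBIDDEN
  assign <- .lsap_min(cost)
  qi <- which(assign[seq_len(m)] <= n)
  pairs <- cbind(qi, assign[qi])
  if (any(cost[cbind(seq_len(N), assign)] >= .FORBIDDEN)) {
    stop("internal error: forbidden cell selected in assignment reduction")
  }
  total <- if (nrow(pairs)) sum(S[pairs]) else 0
  gap_rows <- setdiff(seq_len(m), qi)
  gap_cols <- setdiff(seq_len(n), pairs[, 2L])
  objective <- total +
    (if (length(gap_rows)) sum(S[cbind(gap_rows, n + 1L)]) else 0) +
    (if (length(gap_cols)) sum(S[cbind(m + 1L, gap_cols)]) else 0)
  res <- alignment_result(pairs, "row", total_similarity = total)
  attr(res, "objective") <- objective
  res
}
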