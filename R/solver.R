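## Entropic partial-assignment machinery: log-domain semi-relaxed Sinkhorn,
## alignment inference, and direction selection.

.row_lse <- function(A) {
  # log-sum-exp over rows, -Inf-safe
  M <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  out <- M + log(rowSums(exp(A - M)))
  out[!is.finite(M)] <- -Inf
  out
}

#' Construct an alignment result
#'
#' An injective partial residue correspondence. Gap states never appear as
#' pairs; every index refers to a real residue (1-based).
#'
#' @param pairs Integer matrix with columns `i` (query) and `j` (target); no
#'   index repeats within a column.
#' @param direction `"row"` or `"col"`: which inference direction produced it.
#' @param distances Optional per-pair distances (Angstrom).
#' @param total_similarity Sum of interior similarity over the pairs.
#' @param tm,sp Optional TM-score / SP-score of the alignment.
#' @return An object of class `alignment_result`.
#' @export
alignment_result <- function(pairs, direction = c("row", "col"),
                             distances = NULL, total_similarity = NA_real_,
                             tm = NA_real_, sp = NA_real_) {
  direction <- match.arg(direction)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 0) {
    stopifnot(!anyDuplicated(pairs[, 1L]), !anyDuplicated(pairs[, 2L]),
              all(pairs >= 1L))
  }
  if (is.null(distances)) distances <- rep(NA_real_, nrow(pairs))
  stopifnot(length(distances) == nrow(pairs))
  structure(list(pairs = pairs, direction = direction,
                 distances = as.numeric(distances),
                 total_similarity = total_similarity, tm = tm, sp = sp),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> Nali %d (%s direction), SP %.4f, TM %.4f\n",
              nrow(x$pairs), x$direction, x$sp, x$tm))
  invisible(x)
}

#' Semi-relaxed Sinkhorn solver for the entropic partial assignment
#'
#' Solves the entropy-regularized relaxation of the gap-augmented partial
#' assignment: minimize `sum C_ij P_ij + (1/lambda) sum P_ij log P_ij` over
#' gap-bi-stochastic `P` whose constrained margins are the m real rows (each
#' sums to 1 over all n+1 columns) and the n real columns (each sums to 1 over
#' all m+1 rows); the gap row and gap column margins are free and the
#' gap-to-gap corner is pinned at 1. The iteration alternates row and column
#' scaling of the kernel `exp(-lambda C)` with the gap-state duals frozen at
#' zero, entirely in the log domain so `lambda = 100` is numerically safe.
#'
#' With `gap_modeling = FALSE` the classical entropic LSAP ablation is solved
#' instead: gap states are dropped and only the shorter chain's marginals are
#' constrained (single-sided normalization, exact after one pass); the result
#' is embedded back into the (m+1) x (n+1) container with zero gap mass.
#'
#' @param cost A `cost_matrix` from [build_cost_matrix()].
#' @param params [solver_params()].
#' @return An object of class `coupling`: list with `P` ((m+1) x (n+1)),
#'   `dual_row` (length m), `dual_col` (length n), `iterations_used`,
#'   `converged`, `entropy` (`sum P log P` with `0 log 0 = 0`), `m`, `n`,
#'   `gap_modeling`.
#' @export
sinkhorn_partial <- function(cost, params = solver_params()) {
  stopifnot(inherits(cost, "cost_matrix"), inherits(params, "solver_params"))
  if (!all(is.finite(cost$C))) stop("non-finite entries in cost matrix")
  m <- cost$m
  n <- cost$n
  lam <- params$lambda

  if (!params$gap_modeling) {
    logK <- -lam * cost$C[seq_len(m), seq_len(n), drop = FALSE]
    P <- matrix(0, m + 1L, n + 1L)
    if (m <= n) {
      f <- -.row_lse(logK)
      P[seq_len(m), seq_len(n)] <- exp(logK + f)
      dual_row <- f
      dual_col <- numeric(n)
    } else {
      g <- -.row_lse(t(logK))
      P[seq_len(m), seq_len(n)] <- exp(sweep(logK, 2, g, "+"))
      dual_row <- numeric(m)
      dual_col <- g
    }
    P[m + 1L, n + 1L] <- 1
    return(.new_coupling(P, dual_row, dual_col, 1L, TRUE, m, n, FALSE))
  }

  logK <- -lam * cost$C
  logK[m + 1L, n + 1L] <- -Inf   # corner excluded from all margins
  fit <- .sinkhorn_loop(logK, m, n, params$tol, params$tmax)
  P <- exp(logK + outer(c(fit$f, 0), c(fit$g, 0), "+"))
  P[m + 1L, n + 1L] <- 1
  .new_coupling(P, fit$f, fit$g, fit$iterations, fit$converged, m, n, TRUE)
}

.new_coupling <- function(P, dual_row, dual_col, iterations, converged,
                          m, n, gap_modeling) {
  Pn <- P
  Pn[m + 1L, n + 1L] <- 0
  ent <- sum(ifelse(Pn > 0, Pn * log(Pn), 0))
  structure(list(P = P, dual_row = dual_row, dual_col = dual_col,
                 iterations_used = as.integer(iterations),
                 converged = converged, entropy = ent,
                 m = m, n = n, gap_modeling = gap_modeling),
            class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  cat(sprintf("<coupling> %d x %d (+gaps), %d iterations, converged: %s\n",
              x$m, x$n, x$iterations_used, x$converged))
  invisible(x)
}

#' Infer a discrete alignment from a coupling
#'
#' Row direction: each query residue selects the column holding its maximum
#' coupling mass (first maximum on ties); selecting the gap column leaves the
#' residue unaligned. When several residues select the same target, only the
#' one with the largest mass keeps it (ties: smallest index); the rest become
#' unaligned. Column direction is symmetric. The result is injective both
#' ways.
#'
#' @param coupling A `coupling` from [sinkhorn_partial()].
#' @param direction `"row"` or `"col"`.
#' @return An `alignment_result` (distances and scores unset).
#' @export
infer_alignment <- function(coupling, direction = c("row", "col")) {
  direction <- match.arg(direction)
  m <- coupling$m
  n <- coupling$n
  P <- coupling$P
  if (direction == "row") {
    sel <- .argmax_assign(P[seq_len(m), , drop = FALSE], gap_index = n + 1L)
    pairs <- cbind(sel$from, sel$to)
  } else {
    sel <- .argmax_assign(t(P[, seq_len(n), drop = FALSE]), gap_index = m + 1L)
    pairs <- cbind(sel$to, sel$from)
  }
  alignment_result(pairs, direction)
}

.argmax_assign <- function(Q, gap_index) {
  # Q: one row per "from" element; argmax over columns, gap column drops the
  # element, duplicated targets keep the largest mass (ties: smallest from).
  k <- nrow(Q)
  if (k == 0L) return(list(from = integer(0), to = integer(0)))
  j <- max.col(Q, ties.method = "first")
  val <- Q[cbind(seq_len(k), j)]
  keep <- j != gap_index
  from <- which(keep)
  to <- j[keep]
  val <- val[keep]
  ord <- order(to, -val, from)
  from <- from[ord]
  to <- to[ord]
  first <- !duplicated(to)
  list(from = from[first], to = to[first])
}

#' Choose between row- and column-derived alignments
#'
#' Each candidate is re-superposed by Kabsch on its own pairs and scored by
#' TM-score (normalized by the shorter chain); the higher-scoring alignment is
#' returned, with ties going to the row direction. Candidates with fewer than
#' 3 pairs are scored under the supplied superposition.
#'
#' @param row_aln,col_aln `alignment_result`s inferred from the same coupling.
#' @param query,target The two [chain_structure()]s.
#' @param sup The [superposition()] the coupling was built under.
#' @param norm_length TM-score normalization length; default
#'   `min(length(query), length(target))`.
#' @return The selected `alignment_result`, with its `tm` field populated.
#' @export
select_direction <- function(row_aln, col_aln, query, target, sup,
                             norm_length = min(length(query), length(target))) {
  tmp <- tm_params(norm_length)
  score <- function(aln) {
    p <- aln$pairs
    if (nrow(p) >= 3L) {
      s2 <- kabsch_superpose(query$xyz[p[, 1L], , drop = FALSE],
                             target$xyz[p[, 2L], , drop = FALSE])
      d <- sqrt(rowSums((transform_points(query$xyz[p[, 1L], , drop = FALSE], s2) -
                           target$xyz[p[, 2L], , drop = FALSE])^2))
    } else if (nrow(p) > 0L) {
      d <- sqrt(rowSums((transform_points(query$xyz[p[, 1L], , drop = FALSE], sup) -
                           target$xyz[p[, 2L], , drop = FALSE])^2))
    } else {
      d <- numeric(0)
    }
    tm_score(d, tmp)
  }
  tm_row <- score(row_aln)
  tm_col <- score(col_aln)
  if (tm_row >= tm_col) {
    row_aln$tm <- tm_row
    row_aln
  } else {
    col_aln$tm <- tm_col
    col_aln
  }
}

#' Full alignment pass from a fixed superposition
#'
#' The core pipeline: superposed distances, SP similarity matrix, cost
#' transform, semi-relaxed Sinkhorn, inference in both directions, TM-score
#' direction selection. Distances, total similarity, SP-score and TM-score are
#' populated on the result (distances are measured under the supplied
#' superposition).
#'
#' @param query,target [chain_structure()]s.
#' @param sup [superposition()] mapping query onto target.
#' @param sp [sp_params()].
#' @param solver [solver_params()].
#' @param gap_score Gap score on the similarity scale; default 0.
#' @param epsilon_shift Cost-transform margin; default 0.5.
#' @return An `alignment_result` with attribute `"coupling"`.
#' @export
solve_from_superposition <- function(query, target, sup,
                                     sp = sp_params(),
                                     solver = solver_params(),
                                     gap_score = 0, epsilon_shift = 0.5) {
  dist <- pairwise_distances(query, target, sup)
  sim <- build_similarity_matrix(dist, gap_score, sp)
  cost <- build_cost_matrix(sim, epsilon_shift)
  cp <- sinkhorn_partial(cost, solver)
  row_aln <- infer_alignment(cp, "row")
  col_aln <- infer_alignment(cp, "col")
  best <- select_direction(row_aln, col_aln, query, target, sup)
  p <- best$pairs
  d <- if (nrow(p)) dist[p] else numeric(0)
  best$distances <- d
  best$total_similarity <- if (nrow(p)) sum(sim$S[p]) else 0
  best$sp <- sp_score(d, sp)
  attr(best, "coupling") <- cp
  best
}
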