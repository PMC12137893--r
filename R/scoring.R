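## SP-score similarity model and the gap-augmented similarity / cost matrices.

#' Per-pair SP-score similarity
#'
#' `1 / (1 + d^2/d0^2) - 0.2` for `d < 2 d0` (strictly positive on that
#' range), 0 beyond the cutoff.
#'
#' @param d Distance(s) in Angstrom, all >= 0.
#' @param params [sp_params()].
#' @return Non-negative similarity value(s).
#' @export
residue_similarity <- function(d, params = sp_params()) {
  stopifnot(inherits(params, "sp_params"))
  if (any(d < 0)) stop("negative distance passed to residue_similarity")
  s <- 1 / (1 + (d / params$d0)^2) - 0.2
  s[d >= params$cutoff] <- 0
  s
}

#' Build the gap-augmented similarity matrix S
#'
#' The (m+1) x (n+1) matrix whose interior holds residue-pair similarities,
#' whose last row and column hold the gap score (the reward for leaving a
#' residue unaligned), and whose gap-to-gap corner is fixed at 0.
#'
#' @param dist m x n distance matrix from [pairwise_distances()].
#' @param gap_score Non-negative gap score `g`; default 0, i.e. a residue at
#'   the similarity cutoff ties with a gap.
#' @param params [sp_params()].
#' @return An object of class `similarity_matrix`: list with `S`
#'   ((m+1) x (n+1)), `gap_score`, `m`, `n`.
#' @export
build_similarity_matrix <- function(dist, gap_score = 0, params = sp_params()) {
  stopifnot(is.matrix(dist), gap_score >= 0)
  m <- nrow(dist)
  n <- ncol(dist)
  S <- matrix(gap_score, m + 1L, n + 1L)
  S[seq_len(m), seq_len(n)] <- residue_similarity(dist, params)
  S[m + 1L, n + 1L] <- 0
  structure(list(S = S, gap_score = gap_score, m = m, n = n),
            class = "similarity_matrix")
}

#' Build a similarity matrix from explicit entries
#'
#' Low-level constructor used by the toy-problem generator and tests.
#'
#' @param interior m x n matrix of non-negative similarities.
#' @param gap_col Length-m gap scores for query residues (last column).
#' @param gap_row Length-n gap scores for target residues (last row).
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(interior, gap_col = 0, gap_row = 0) {
  interior <- as.matrix(interior)
  m <- nrow(interior)
  n <- ncol(interior)
  gap_col <- rep_len(gap_col, m)
  gap_row <- rep_len(gap_row, n)
  stopifnot(all(interior >= 0), all(gap_col >= 0), all(gap_row >= 0))
  S <- matrix(0, m + 1L, n + 1L)
  S[seq_len(m), seq_len(n)] <- interior
  S[seq_len(m), n + 1L] <- gap_col
  S[m + 1L, seq_len(n)] <- gap_row
  structure(list(S = S, gap_score = gap_row[1L], m = m, n = n),
            class = "similarity_matrix")
}

#' Transform similarities into a non-negative cost matrix
#'
#' The assignment maximization is turned into a minimization through dual
#' shifts. With every row/column shift set to `c = max(S) + epsilon_shift` and
#' the gap-gap coefficient fixed at 0: interior `C_ij = 2c - S_ij`, gap column
#' `C = c - S`, gap row `C = c - S`, corner `C = 0`. All entries are >= 0 by
#' construction (the minimum over non-corner cells is exactly `epsilon_shift`
#' when the maximum of S is interior).
#'
#' @param sim A `similarity_matrix`.
#' @param epsilon_shift Positive margin added to `max(S)`; default 0.5.
#' @return An object of class `cost_matrix`: list with `C`, `c_shift`,
#'   `epsilon_shift`, `m`, `n`.
#' @export
build_cost_matrix <- function(sim, epsilon_shift = 0.5) {
  stopifnot(inherits(sim, "similarity_matrix"), epsilon_shift > 0)
  m <- sim$m
  n <- sim$n
  S <- sim$S
  cc <- max(S) + epsilon_shift
  C <- matrix(0, m + 1L, n + 1L)
  C[seq_len(m), seq_len(n)] <- 2 * cc - S[seq_len(m), seq_len(n)]
  C[seq_len(m), n + 1L] <- cc - S[seq_len(m), n + 1L]
  C[m + 1L, seq_len(n)] <- cc - S[m + 1L, seq_len(n)]
  structure(list(C = C, c_shift = cc, epsilon_shift = epsilon_shift,
                 m = m, n = n),
            class = "cost_matrix")
}

#' Aggregate SP-score of an alignment
#'
#' `SP = L^-(1 - alpha) * sum_{d < 2 d0} (1 / (1 + d^2/d0^2) - 0.2)`, where
#' `L` counts the aligned core pairs (those inside the cutoff). Pairs at or
#' beyond the cutoff contribute nothing and do not dilute the normalization.
#' Returns 0 when no pair is inside the cutoff.
#'
#' @param distances Per-pair distances (Angstrom) of an injective
#'   correspondence.
#' @param params [sp_params()].
#' @return Non-negative SP-score.
#' @export
sp_score <- function(distances, params = sp_params()) {
  stopifnot(inherits(params, "sp_params"))
  core <- distances[distances < params$cutoff]
  L <- length(core)
  if (L == 0L) return(0)
  sum(residue_similarity(core, params)) / L^(1 - params$alpha)
}
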