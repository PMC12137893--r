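## Built-in superposition engine: fragment-window seeding and alternating
## alignment/re-superposition refinement. A deliberately simple stand-in for
## full topology-(in)dependent superposition programs; for fidelity to an
## external engine, import its rotation matrix instead.

.greedy_core_sp <- function(dist, sp) {
  # injective greedy pick of closest pairs inside the cutoff; SP-score of the
  # picked distances. Used only to rank candidate superpositions.
  hits <- which(dist < sp$cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(list(sp = 0, n = 0L))
  d <- dist[hits]
  ord <- order(d)
  hits <- hits[ord, , drop = FALSE]
  d <- d[ord]
  used_i <- logical(nrow(dist))
  used_j <- logical(ncol(dist))
  keep <- logical(length(d))
  for (k in seq_along(d)) {
    i <- hits[k, 1L]
    j <- hits[k, 2L]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  list(sp = sp_score(d[keep], sp), n = sum(keep))
}

#' Candidate superpositions from gapless fragment windows
#'
#' Kabsch-fits every pair of gapless `seed_window`-long fragments on a
#' `seed_stride` offset grid and ranks the resulting rigid maps by the
#' SP-score of a greedy injective pairing of the induced full-chain distance
#' table. If either chain is shorter than the window, a single global gapless
#' Kabsch seed is returned instead.
#'
#' @param query,target [chain_structure()]s.
#' @param params [refine_params()].
#' @param sp [sp_params()] used for ranking.
#' @return List of [superposition()]s, best first, each with attribute
#'   `"seed_sp"`.
#' @export
seed_superpositions <- function(query, target, params = refine_params(),
                                sp = sp_params()) {
  m <- length(query)
  n <- length(target)
  w <- params$seed_window
  if (m < w || n < w) {
    k <- min(m, n)
    ns_log("INFO", "chain shorter than seed window: single global Kabsch seed")
    sup <- kabsch_superpose(query$xyz[seq_len(k), , drop = FALSE],
                            target$xyz[seq_len(k), , drop = FALSE])
    attr(sup, "seed_sp") <- .greedy_core_sp(
      pairwise_distances(query, target, sup), sp)$sp
    return(list(sup))
  }
  qo <- unique(c(seq(1L, m - w + 1L, by = params$seed_stride), m - w + 1L))
  to <- unique(c(seq(1L, n - w + 1L, by = params$seed_stride), n - w + 1L))
  seeds <- vector("list", length(qo) * length(to))
  scores <- numeric(length(seeds))
  k <- 0L
  for (a in qo) {
    for (b in to) {
      k <- k + 1L
      sup <- kabsch_superpose(query$xyz[a:(a + w - 1L), , drop = FALSE],
                              target$xyz[b:(b + w - 1L), , drop = FALSE])
      scores[k] <- .greedy_core_sp(pairwise_distances(query, target, sup), sp)$sp
      attr(sup, "seed_sp") <- scores[k]
      seeds[[k]] <- sup
    }
  }
  seeds[order(scores, decreasing = TRUE)]
}

#' Alternate alignment and re-superposition to a fixed point
#'
#' From an initial rigid map, repeatedly solve the entropic partial assignment
#' and re-fit the superposition by Kabsch on the resulting pairs, until the
#' pair set repeats or `max_rounds` is hit. The round with the highest
#' SP-score is kept, so the returned score never falls below round one. The
#' loop is fully deterministic.
#'
#' @param query,target [chain_structure()]s.
#' @param initial Starting [superposition()].
#' @param sp [sp_params()].
#' @param solver [solver_params()].
#' @param params [refine_params()].
#' @param gap_score,epsilon_shift Passed to [solve_from_superposition()].
#' @return List with `superposition`, `alignment`, `rounds`.
#' @export
refine_alternating <- function(query, target, initial,
                               sp = sp_params(), solver = solver_params(),
                               params = refine_params(),
                               gap_score = 0, epsilon_shift = 0.5) {
  sup <- initial
  best <- NULL
  best_sup <- initial
  seen <- character(0)
  rounds <- 0L
  for (r in seq_len(params$max_rounds)) {
    aln <- solve_from_superposition(query, target, sup, sp, solver,
                                    gap_score, epsilon_shift)
    rounds <- r
    if (is.null(best) || aln$sp > best$sp) {
      best <- aln
      best_sup <- sup
    }
    if (nrow(aln$pairs) < 3L) break
    sig <- paste(aln$pairs[, 1L], aln$pairs[, 2L], sep = ":", collapse = ",")
    if (sig %in% seen) break
    seen <- c(seen, sig)
    sup <- kabsch_superpose(query$xyz[aln$pairs[, 1L], , drop = FALSE],
                            target$xyz[aln$pairs[, 2L], , drop = FALSE])
  }
  if (is.null(best)) {
    best <- alignment_result(matrix(integer(0), 0, 2), "row",
                             total_similarity = 0, sp = 0, tm = 0)
  }
  list(superposition = best_sup, alignment = best, rounds = rounds)
}

#' End-to-end structure alignment
#'
#' If no superposition is supplied, fragment seeds are generated, the top
#' `keep_top` are refined by [refine_alternating()], and the highest-SP-score
#' outcome wins. With a supplied superposition, seeding is skipped and
#' refinement starts there.
#'
#' @param query,target [chain_structure()]s.
#' @param sup Optional [superposition()] (e.g. imported from an external
#'   engine via [read_superposition_matrix()]).
#' @param sp,solver,refine Parameter objects.
#' @param gap_score,epsilon_shift Scoring-matrix parameters.
#' @return List with `superposition`, `alignment`, `rounds`.
#' @export
align_structures <- function(query, target, sup = NULL,
                             sp = sp_params(), solver = solver_params(),
                             refine = refine_params(),
                             gap_score = 0, epsilon_shift = 0.5) {
  if (!is.null(sup)) {
    return(refine_alternating(query, target, sup, sp, solver, refine,
                              gap_score, epsilon_shift))
  }
  seeds <- seed_superpositions(query, target, refine, sp)
  seeds <- seeds[seq_len(min(refine$keep_top, length(seeds)))]
  best <- NULL
  for (s in seeds) {
    cand <- refine_alternating(query, target, s, sp, solver, refine,
                               gap_score, epsilon_shift)
    if (is.null(best) || cand$alignment$sp > best$alignment$sp) best <- cand
  }
  best
}
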