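#' SP-score parameters
#'
#' The SP-score similarity model scores a superposed residue pair at distance
#' `d` (Angstrom) as `1 / (1 + d^2 / d0^2) - 0.2` when `d < 2 * d0`, and 0
#' otherwise. `d0` is a fixed, size-independent normalization (4 Angstrom by
#' default), so only genuinely close pairs contribute regardless of protein
#' size. `alpha` controls the length normalization `L^(1 - alpha)` of the
#' aggregate score.
#'
#' @param alpha Dimensionless scale factor in (0, 1); default 0.3.
#' @param d0 Distance normalization in Angstrom; default 4.
#' @return An object of class `sp_params` with fields `alpha`, `d0` and the
#'   derived inclusion `cutoff = 2 * d0`.
#' @export
sp_params <- function(alpha = 0.3, d0 = 4) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(d0), length(d0) == 1L, d0 > 0)
  structure(list(alpha = alpha, d0 = d0, cutoff = 2 * d0),
            class = "sp_params")
}

#' Solver parameters for the entropic partial assignment
#'
#' @param lambda Entropy sharpness (> 0). The entropy term enters the objective
#'   with weight `1 / lambda`, so larger values approach the exact assignment.
#'   Default 100.
#' @param tol Maximum allowed marginal violation at convergence. Default 1e-6.
#' @param tmax Iteration cap. Default 5000.
#' @param gap_modeling If `TRUE` (default) solve the gap-augmented partial
#'   problem (epLSAP); if `FALSE`, the classical entropic LSAP ablation with no
#'   gap states: only the shorter chain's marginals are constrained, forcing
#'   every one of its residues to carry unit mass.
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(lambda = 100, tol = 1e-6, tmax = 5000,
                          gap_modeling = TRUE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(tol), tol > 0,
            is.numeric(tmax), tmax >= 1,
            is.logical(gap_modeling), length(gap_modeling) == 1L)
  structure(list(lambda = lambda, tol = tol, tmax = as.integer(tmax),
                 gap_modeling = gap_modeling),
            class = "solver_params")
}

#' Parameters for fragment seeding and alternating refinement
#'
#' Initial superpositions are produced by Kabsch-fitting gapless fragment
#' windows of the two chains on a stride grid; the best seeds are then refined
#' by alternating alignment and re-superposition.
#'
#' @param seed_window Fragment length for seeding (>= 4). Default 20.
#' @param seed_stride Offset step of the window grid. Default 5.
#' @param max_rounds Cap on alignment/superposition alternations. Default 10.
#' @param keep_top Number of ranked seeds refined fully. Default 5.
#' @return An object of class `refine_params`.
#' @export
refine_params <- function(seed_window = 20, seed_stride = 5, max_rounds = 10,
                          keep_top = 5) {
  stopifnot(seed_window >= 4, seed_stride >= 1, max_rounds >= 1, keep_top >= 1)
  structure(list(seed_window = as.integer(seed_window),
                 seed_stride = as.integer(seed_stride),
                 max_rounds = as.integer(max_rounds),
                 keep_top = as.integer(keep_top)),
            class = "refine_params")
}

#' TM-score parameters
#'
#' @param norm_length Normalization length `L` (>= 1); conventionally the
#'   length of the shorter chain.
#' @return An object of class `tm_params` with fields `norm_length` and the
#'   derived scale `d0_tm = max(0.5, 1.24 * (L - 15)^(1/3) - 1.8)`.
#' @export
tm_params <- function(norm_length) {
  stopifnot(is.numeric(norm_length), length(norm_length) == 1L,
            norm_length >= 1)
  L <- as.integer(norm_length)
  x <- L - 15
  d0 <- max(0.5, 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8)
  structure(list(norm_length = L, d0_tm = d0), class = "tm_params")
}
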