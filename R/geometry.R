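## Rigid-body mathematics: Kabsch superposition, transforms, distances,
## TM-score.

.as_coords <- function(x) {
  if (inherits(x, "chain_structure")) return(x$xyz)
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3L)
  m
}

#' Optimal rigid superposition (Kabsch)
#'
#' Closed-form SVD solution for the proper rotation and translation minimizing
#' the RMSD between `moving` (after transformation) and `fixed`. A reflection
#' in the SVD solution is corrected by flipping the sign of the smallest
#' singular direction.
#'
#' @param moving,fixed n x 3 coordinate matrices (or [chain_structure()]s) of
#'   equal length n >= 3, not all collinear.
#' @return A [superposition()] with attribute `"rmsd"`, the residual RMSD.
#' @export
kabsch_superpose <- function(moving, fixed) {
  A <- .as_coords(moving)
  B <- .as_coords(fixed)
  if (nrow(A) != nrow(B)) stop("point lists differ in length")
  if (nrow(A) < 3L) stop("need at least 3 point pairs for a superposition")
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.vector(R %*% ca)
  sup <- superposition(R, tr)
  resid <- sweep(A %*% t(R), 2, tr, "+") - B
  attr(sup, "rmsd") <- sqrt(mean(rowSums(resid^2)))
  sup
}

#' Apply a rigid superposition to points
#'
#' @param points n x 3 coordinate matrix (or [chain_structure()]).
#' @param sup A [superposition()].
#' @return n x 3 matrix of transformed coordinates `R x + t`.
#' @export
transform_points <- function(points, sup) {
  stopifnot(inherits(sup, "superposition"))
  X <- .as_coords(points)
  sweep(X %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Invert a rigid superposition
#'
#' @param sup A [superposition()].
#' @return The inverse map `(R', t') = (R^T, -R^T t)`.
#' @export
invert_superposition <- function(sup) {
  Rt <- t(sup$rotation)
  superposition(Rt, -as.vector(Rt %*% sup$translation))
}

#' All-vs-all Cα distances after superposition
#'
#' @param query,target [chain_structure()]s of lengths m and n.
#' @param sup [superposition()] mapping the query frame onto the target frame.
#' @return m x n matrix with entry (i, j) = Euclidean distance between
#'   superposed query residue i and target residue j, in Angstrom.
#' @export
pairwise_distances <- function(query, target, sup = superposition()) {
  q <- transform_points(query, sup)
  t_ <- .as_coords(target)
  # per-coordinate differences: exact at zero, unlike the Gram-matrix identity
  d2 <- outer(q[, 1], t_[, 1], "-")^2 +
    outer(q[, 2], t_[, 2], "-")^2 +
    outer(q[, 3], t_[, 3], "-")^2
  sqrt(d2)
}

#' TM-score of an aligned pair set
#'
#' Length-normalized structural similarity in `[0, 1]`:
#' `(1/L) * sum 1 / (1 + (d_i/d0)^2)` with
#' `d0 = max(0.5, 1.24 (L - 15)^(1/3) - 1.8)`. Used here only to choose
#' between row- and column-derived alignments, normalized by the shorter
#' chain by default.
#'
#' @param distances Per-pair distances in Angstrom (may be empty).
#' @param params A [tm_params()] giving the normalization length.
#' @return TM-score in `[0, 1]`; 0 for an empty pair set.
#' @export
tm_score <- function(distances, params) {
  stopifnot(inherits(params, "tm_params"))
  if (length(distances) == 0L) return(0)
  stopifnot(all(distances >= 0))
  sum(1 / (1 + (distances / params$d0_tm)^2)) / params$norm_length
}
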