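## Ground-truthed synthetic fixtures: ideal helical traces, non-sequential
## rearrangements with known correspondence, coordinate noise, and letter-toy
## similarity problems.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Ideal helical Cα trace
#'
#' Textbook alpha-helix Cα geometry: radius 2.3 Angstrom, rise 1.5 Angstrom
#' per residue, 100 degrees of turn per residue, axis along z. Coordinates are
#' fully determined by `n`; the seed only randomizes the residue letters.
#'
#' @param n Residue count (>= 4).
#' @param seed Seed for the amino-acid labels. Default 1.
#' @param chain_id Chain label; default `"A"`.
#' @return A [chain_structure()].
#' @export
make_helix_chain <- function(n, seed = 1, chain_id = "A") {
  if (n < 4) stop("a helical trace needs at least 4 residues")
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  aa <- .with_seed(seed, sample(setdiff(names(.aa1to3), "X"), n, replace = TRUE))
  chain_structure(chain_id, seq_len(n), rep("", n), aa, xyz)
}

#' Non-sequential rearrangement with known correspondence
#'
#' Permutes the residue record order of a chain while leaving every
#' coordinate untouched, producing a target whose 3D structure is identical
#' but whose chain topology differs — the defining situation for
#' non-sequential alignment. `circular` moves the block from `cut` onward to
#' the front; `segment_swap` exchanges the blocks `[1, cut[1])` and
#' `[cut[1], cut[2])`, leaving the tail in place. The target is renumbered
#' 1..n in its new order.
#'
#' @param chain A [chain_structure()].
#' @param mode `"circular"` or `"segment_swap"`.
#' @param cut For `circular`, a single 1-based index `c` with `1 < c <= n`
#'   (the new first residue); for `segment_swap`, bounds `c(s, e)` with
#'   `1 < s < e <= n + 1` delimiting the two swapped blocks.
#' @param noise_sigma Isotropic Gaussian noise (Angstrom) applied to the
#'   target after rearrangement; default 0.
#' @param seed Seed for the noise. Default 1.
#' @return List of class `ground_truth_pair`: `query`, `target`, `truth_map`
#'   (two-column matrix, query index -> target index), `rearrangement`,
#'   `noise_sigma`.
#' @export
rearrange_segments <- function(chain, mode = c("circular", "segment_swap"),
                               cut, noise_sigma = 0, seed = 1) {
  mode <- match.arg(mode)
  n <- length(chain)
  if (mode == "circular") {
    stopifnot(length(cut) == 1L)
    if (cut <= 1 || cut > n) stop("circular cut must lie strictly inside the chain")
    ord <- c(cut:n, 1:(cut - 1))   # original indices in target order
  } else {
    stopifnot(length(cut) == 2L)
    s <- cut[1L]
    e <- cut[2L]
    if (s <= 1 || e <= s || e > n + 1) stop("segment bounds must be strictly inside the chain")
    tail_idx <- if (e <= n) e:n else integer(0)
    ord <- c(s:(e - 1), 1:(s - 1), tail_idx)
  }
  target <- chain_structure(chain$chain_id,
                            seq_len(n),
                            chain$icode[ord],
                            chain$aa[ord],
                            chain$xyz[ord, , drop = FALSE])
  if (noise_sigma > 0) target <- jitter_coords(target, noise_sigma, seed)
  truth <- cbind(i = ord, j = seq_len(n))
  truth <- truth[order(truth[, 1L]), , drop = FALSE]
  structure(list(query = chain, target = target, truth_map = truth,
                 rearrangement = mode, noise_sigma = noise_sigma),
            class = "ground_truth_pair")
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param chain A [chain_structure()].
#' @param sigma Standard deviation per coordinate (Angstrom), >= 0.
#' @param seed Seed; output is deterministic given (chain, sigma, seed).
#' @return A [chain_structure()] with perturbed coordinates.
#' @export
jitter_coords <- function(chain, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(chain)
  n <- length(chain)
  noise <- .with_seed(seed, matrix(rnorm(3 * n, sd = sigma), n, 3))
  chain_structure(chain$chain_id, chain$resno, chain$icode, chain$aa,
                  chain$xyz + noise)
}

#' Letter-matching toy similarity problem
#'
#' Builds the gap-augmented similarity matrix for aligning two strings where
#' identical letters (case-insensitively) score `match`, others `mismatch`,
#' and gap states score `gap`. A minimal, fully enumerable instance of the
#' non-sequential partial assignment.
#'
#' @param s1,s2 Non-empty strings.
#' @param match,mismatch,gap Scores; defaults 1, 0, 0.
#' @return A `similarity_matrix`.
#' @export
letter_problem <- function(s1, s2, match = 1, mismatch = 0, gap = 0) {
  a <- strsplit(tolower(s1), "")[[1L]]
  b <- strsplit(tolower(s2), "")[[1L]]
  if (!length(a) || !length(b)) stop("both strings must be non-empty")
  interior <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
  similarity_matrix(interior, gap_col = gap, gap_row = gap)
}
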