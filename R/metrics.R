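## Alignment quality metrics: reference-independent (Nali, RMSD, SO, SO_th)
## and reference-dependent (EQR, agreement).

#' RMSD over aligned pairs
#'
#' @param distances Non-empty vector of per-pair distances (Angstrom).
#' @return `sqrt(mean(distances^2))`.
#' @export
aligned_rmsd <- function(distances) {
  if (length(distances) == 0L) stop("RMSD undefined for an empty alignment")
  sqrt(mean(distances^2))
}

#' Structure overlap (SO)
#'
#' Percentage of aligned pairs at or under the threshold; the boundary is
#' inclusive (`d <= t`). An empty alignment yields 0 by convention (logged).
#'
#' @param distances Per-pair distances (Angstrom).
#' @param threshold Inclusion threshold; default 3.5.
#' @return Percent in `[0, 100]`.
#' @export
structure_overlap <- function(distances, threshold = 3.5) {
  if (length(distances) == 0L) {
    ns_log("INFO", "structure_overlap of empty alignment: 0 by convention")
    return(0)
  }
  100 * mean(distances <= threshold)
}

#' Structure overlap across a threshold grid
#'
#' @param distances Per-pair distances (Angstrom).
#' @param thresholds Ascending thresholds; default 3.0 to 7.0 by 0.5.
#' @return Data frame with columns `threshold`, `so`.
#' @export
so_curve <- function(distances, thresholds = seq(3, 7, by = 0.5)) {
  stopifnot(!is.unsorted(thresholds))
  data.frame(threshold = thresholds,
             so = vapply(thresholds, function(t) {
               structure_overlap(distances, t)
             }, numeric(1L)))
}

.pair_keys <- function(pairs) paste(pairs[, 1L], pairs[, 2L], sep = ":")

#' Agreement with a curated reference alignment
#'
#' EQR counts the aligned residue pairs shared, as exact (i, j) matches, with
#' the reference; agreement is EQR as a percentage of the reference length.
#'
#' @param aln An `alignment_result`, or a two-column pair matrix.
#' @param reference Non-empty two-column matrix of reference pairs (injective
#'   both ways).
#' @return List with `eqr` (integer) and `agreement` (percent).
#' @export
eqr_agreement <- function(aln, reference) {
  pairs <- if (inherits(aln, "alignment_result")) aln$pairs else
    matrix(as.integer(aln), ncol = 2L)
  reference <- matrix(as.integer(reference), ncol = 2L)
  if (nrow(reference) == 0L) stop("empty reference alignment")
  if (anyDuplicated(reference[, 1L]) || anyDuplicated(reference[, 2L])) {
    stop("reference alignment is not injective")
  }
  eqr <- sum(.pair_keys(pairs) %in% .pair_keys(reference))
  list(eqr = as.integer(eqr), agreement = 100 * eqr / nrow(reference))
}

#' Read a reference alignment from TSV
#'
#' Two integer columns (query residue number, target residue number),
#' `#`-comment lines allowed; pairs are returned in file order and validated
#' injective.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with columns `i`, `j` (possibly 0 rows).
#' @export
read_reference_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("reference file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  seen_i <- integer(0)
  seen_j <- integer(0)
  for (k in data_idx) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.integer(toks[1:2]))
    if (length(toks) < 2L || anyNA(vals)) {
      stop(sprintf("%s line %d: expected two integer columns", path, k))
    }
    if (vals[1L] %in% seen_i || vals[2L] %in% seen_j) {
      stop(sprintf("%s line %d: duplicate residue breaks injectivity", path, k))
    }
    seen_i <- c(seen_i, vals[1L])
    seen_j <- c(seen_j, vals[2L])
    out <- rbind(out, vals)
  }
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Full metrics report for an alignment
#'
#' @param aln An `alignment_result` with distances populated.
#' @param reference Optional reference pair matrix for EQR/agreement.
#' @param so_threshold SO threshold; default 3.5.
#' @param thresholds SO_th grid; default 3.0 to 7.0 by 0.5.
#' @return List with `nali`, `rmsd`, `so`, `so_curve`, and when a reference is
#'   supplied, `eqr` and `agreement`.
#' @export
metrics_report <- function(aln, reference = NULL, so_threshold = 3.5,
                           thresholds = seq(3, 7, by = 0.5)) {
  d <- aln$distances
  rep_ <- list(
    nali = nrow(aln$pairs),
    rmsd = if (length(d)) aligned_rmsd(d) else NA_real_,
    so = structure_overlap(d, so_threshold),
    so_curve = so_curve(d, thresholds)
  )
  if (!is.null(reference)) {
    ea <- eqr_agreement(aln, reference)
    rep_$eqr <- ea$eqr
    rep_$agreement <- ea$agreement
  }
  rep_
}
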