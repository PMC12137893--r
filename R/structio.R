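## Cα-trace structures, PDB and rotation-matrix I/O.

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)
.aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

#' Construct a Cα chain structure
#'
#' Ordered Cα residues of one protein chain: the unit every alignment operation
#' works on. Residue order is the file (record) order; internal indices are
#' 1-based and contiguous, while `resno`/`icode` keep the author numbering for
#' all file output.
#'
#' @param chain_id Single-character chain label.
#' @param resno Integer vector of author residue numbers.
#' @param icode Character vector of insertion codes (`""` when absent).
#' @param aa Character vector of one-letter amino-acid codes.
#' @param xyz Numeric matrix, one row per residue, 3 columns of Angstrom
#'   coordinates; all entries must be finite.
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, resno, icode, aa, xyz) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n >= 1L, ncol(xyz) == 3L, all(is.finite(xyz)),
            length(resno) == n, length(aa) == n)
  if (missing(icode) || is.null(icode)) icode <- rep("", n)
  stopifnot(length(icode) == n)
  dimnames(xyz) <- NULL
  structure(list(chain_id = as.character(chain_id)[1L],
                 resno = as.integer(resno),
                 icode = as.character(icode),
                 aa = as.character(aa),
                 xyz = xyz),
            class = "chain_structure")
}

#' @export
length.chain_structure <- function(x) nrow(x$xyz)

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s, %d CA residues (%s...)\n",
              x$chain_id, length(x), paste(utils::head(x$aa, 8), collapse = "")))
  invisible(x)
}

#' Construct a rigid superposition
#'
#' A proper rotation plus translation mapping query-frame coordinates onto the
#' target frame: `y = R x + t`.
#'
#' @param rotation 3x3 orthogonal matrix with determinant +1 (checked to
#'   `tol`).
#' @param translation Length-3 numeric vector (Angstrom).
#' @param tol Orthogonality/determinant tolerance. Default 1e-6.
#' @return An object of class `superposition`.
#' @export
superposition <- function(rotation = diag(3), translation = c(0, 0, 0),
                          tol = 1e-6) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho > tol) {
    stop(sprintf("rotation is not orthogonal (max deviation %.3g > %.3g)",
                 ortho, tol))
  }
  if (det(rotation) < 0) {
    stop("rotation has determinant -1 (reflection), not a proper rotation")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "superposition")
}

#' Read Cα coordinates from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records of the first model only; one entry
#' per residue bearing a Cα atom. For alternate locations the first occurrence
#' wins; residues without a Cα are skipped. Both decisions are logged at INFO.
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain to extract; `NULL` (default) takes the first chain
#'   seen in the file.
#' @return A [chain_structure()].
#' @export
read_ca_structure <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  # first model only
  first_model <- grep("^MODEL", lines)
  if (length(first_model) >= 1L) {
    endm <- grep("^(ENDMDL|END\\s*$|END$)", lines)
    endm <- endm[endm > first_model[1L]]
    last <- if (length(endm)) endm[1L] else length(lines)
    if (length(first_model) > 1L) {
      ns_log("INFO", "multiple models in %s: keeping MODEL 1 only", path)
    }
    lines <- lines[seq(first_model[1L], last)]
  }

  atoms <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(atoms)) stop(sprintf("no ATOM records in %s", path))

  name <- trimws(substr(atoms, 13, 16))
  ca <- atoms[name == "CA"]
  if (!length(ca)) stop(sprintf("no CA atoms in %s", path))

  ch <- substr(ca, 22, 22)
  if (is.null(chain_id)) {
    chain_id <- ch[1L]
  } else if (!any(ch == chain_id)) {
    stop(sprintf("chain '%s' not found in %s (chains present: %s)",
                 chain_id, path, paste(unique(ch), collapse = ", ")))
  }
  ca <- ca[ch == chain_id]

  altloc <- substr(ca, 17, 17)
  resname <- trimws(substr(ca, 18, 20))
  resno <- as.integer(trimws(substr(ca, 23, 26)))
  icode <- sub(" ", "", substr(ca, 27, 27), fixed = TRUE)
  x <- as.numeric(substr(ca, 31, 38))
  y <- as.numeric(substr(ca, 39, 46))
  z <- as.numeric(substr(ca, 47, 54))
  if (anyNA(resno) || anyNA(x) || anyNA(y) || anyNA(z)) {
    stop(sprintf("malformed ATOM record(s) in %s", path))
  }

  key <- paste(resno, icode, sep = "|")
  keep <- !duplicated(key)
  if (any(!keep)) {
    ns_log("INFO", "chain %s: %d duplicate CA (altloc) record(s) dropped, first occurrence kept",
           chain_id, sum(!keep))
  }
  if (any(grepl("^HETATM", ca[keep]))) {
    ns_log("INFO", "chain %s: HETATM CA record(s) accepted (e.g. MSE)", chain_id)
  }
  aa <- unname(.aa3to1[resname[keep]])
  aa[is.na(aa)] <- "X"
  if (sum(keep) < 1L) stop(sprintf("zero CA residues for chain '%s'", chain_id))
  chain_structure(chain_id, resno[keep], icode[keep], aa,
                  cbind(x, y, z)[keep, , drop = FALSE])
}

#' Write a Cα-only PDB file
#'
#' Emits standard fixed-column ATOM records (occupancy 1.00, B-factor 0.00),
#' one CA per residue, so synthetic fixtures can round-trip through the full
#' I/O path.
#'
#' @param chain A [chain_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- length(chain)
  res3 <- unname(.aa1to3[chain$aa])
  res3[is.na(res3)] <- "UNK"
  ic <- ifelse(chain$icode == "", " ", substr(chain$icode, 1, 1))
  rec <- sprintf("ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
                 seq_len(n), res3, substr(chain$chain_id, 1, 1),
                 chain$resno, ic,
                 chain$xyz[, 1], chain$xyz[, 2], chain$xyz[, 3])
  writeLines(c(rec, "TER", "END"), path)
  invisible(path)
}

#' Read a rigid-superposition matrix file
#'
#' Reads the rotation-file dialect used by common alignment tools (`-m`
#' output): comment/header lines are ignored; the three data rows are
#' `i t(i) u(i,1) u(i,2) u(i,3)` for `i` in 0..2, whitespace-separated, and
#' encode the map `y = t + U x`.
#'
#' @param path Path to the matrix file.
#' @param tol Orthogonality tolerance for the parsed rotation. Default 1e-3.
#' @return A [superposition()].
#' @export
read_superposition_matrix <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rot <- matrix(NA_real_, 3, 3)
  tr <- rep(NA_real_, 3)
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 5L) next
    vals <- suppressWarnings(as.numeric(toks[1:5]))
    if (anyNA(vals)) next
    i <- vals[1L]
    if (!(i %in% c(0, 1, 2))) next
    r <- as.integer(i) + 1L
    tr[r] <- vals[2L]
    rot[r, ] <- vals[3:5]
  }
  if (anyNA(rot) || anyNA(tr)) {
    stop(sprintf("fewer than 3 parseable rotation rows in %s", path))
  }
  ortho <- max(abs(crossprod(rot) - diag(3)))
  if (ortho > tol) {
    stop(sprintf("parsed rotation not orthogonal (deviation %.3g > %.3g)",
                 ortho, tol))
  }
  if (det(rot) < 0) stop("parsed matrix is a reflection (determinant -1)")
  superposition(rot, tr, tol = tol)
}

#' Write a rigid-superposition matrix file
#'
#' Inverse of [read_superposition_matrix()]; floats carry 17 significant
#' digits so the round trip is exact to double precision.
#'
#' @param sup A [superposition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposition_matrix <- function(sup, path) {
  stopifnot(inherits(sup, "superposition"))
  hdr <- c("------ The rotation matrix to rotate structure 1 to structure 2 ------",
           "i          t(i)         u(i,1)         u(i,2)         u(i,3)")
  rows <- vapply(0:2, function(i) {
    r <- i + 1L
    sprintf("%d %s %s %s %s", i,
            formatC(sup$translation[r], digits = 17, format = "g"),
            formatC(sup$rotation[r, 1], digits = 17, format = "g"),
            formatC(sup$rotation[r, 2], digits = 17, format = "g"),
            formatC(sup$rotation[r, 3], digits = 17, format = "g"))
  }, character(1L))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a human-readable alignment report and residue map
#'
#' The report carries a summary header (Nali, RMSD, SO, SP-score, TM-score,
#' lambda) followed by a tab-separated correspondence map in author residue
#' numbering with per-pair distances to three decimals.
#'
#' @param result An `alignment_result` (see [infer_alignment()]).
#' @param qs,ts Query and target [chain_structure()]s the result refers to.
#' @param path Output path.
#' @param lambda Entropy parameter used, echoed in the header (optional).
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(result, qs, ts, path, lambda = NA) {
  stopifnot(inherits(result, "alignment_result"),
            inherits(qs, "chain_structure"), inherits(ts, "chain_structure"))
  p <- result$pairs
  if (nrow(p) > 0 &&
      (max(p[, 1]) > length(qs) || max(p[, 2]) > length(ts) || min(p) < 1)) {
    stop("alignment refers to residue indices out of range for the chains")
  }
  nali <- nrow(p)
  d <- result$distances
  rmsd <- if (nali > 0) aligned_rmsd(d) else NA_real_
  so <- structure_overlap(d)
  hdr <- c(
    "# nsalign alignment report",
    sprintf("# query: chain %s (%d residues)   target: chain %s (%d residues)",
            qs$chain_id, length(qs), ts$chain_id, length(ts)),
    sprintf("# Nali: %d", nali),
    sprintf("# RMSD: %s", if (is.na(rmsd)) "NA" else sprintf("%.3f", rmsd)),
    sprintf("# SO: %.1f", so),
    sprintf("# SP-score: %.4f", result$sp),
    sprintf("# TM-score: %.4f", result$tm),
    sprintf("# lambda: %s", as.character(lambda)),
    sprintf("# direction: %s", result$direction),
    "#query_res\ttarget_res\tdistance"
  )
  rows <- if (nali > 0) {
    sprintf("%d\t%d\t%.3f", qs$resno[p[, 1]], ts$resno[p[, 2]], d)
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
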