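# Independent oracles and small fixture builders shared across the suite.
# Nothing here shares code paths with the implementations under test.

# Brute-force enumeration of every partial injective map; returns the maximum
# of the full objective (interior similarities plus gap scores of everything
# unmatched).
enumerate_plsap_total <- function(sim) {
  S <- sim$S
  m <- sim$m
  n <- sim$n
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > m) {
      free <- setdiff(seq_len(n), used)
      tot <- acc + if (length(free)) sum(S[m + 1, free]) else 0
      if (tot > best) best <<- tot
      return(invisible(NULL))
    }
    rec(i + 1L, used, acc + S[i, n + 1])          # row i takes its gap
    for (j in setdiff(seq_len(n), used)) {
      rec(i + 1L, c(used, j), acc + S[i, j])
    }
    invisible(NULL)
  }
  rec(1L, integer(0), 0)
  best
}

# Probability-domain semi-relaxed Sinkhorn (independent of the log-domain
# implementation): scale rows 1..m and columns 1..n of exp(-lambda C) with the
# gap-state scalings frozen at 1.
plain_sinkhorn <- function(C, m, n, lambda, iters = 200000, tol = 1e-12) {
  K <- exp(-lambda * C)
  v <- rep(1, n)
  u <- rep(1, m)
  for (t in seq_len(iters)) {
    u <- 1 / (K[seq_len(m), seq_len(n), drop = FALSE] %*% v + K[seq_len(m), n + 1])
    v_new <- 1 / (crossprod(K[seq_len(m), seq_len(n), drop = FALSE], u) + K[m + 1, seq_len(n)])
    delta <- max(abs(v_new - v))
    v <- as.vector(v_new)
    if (delta < tol) break
  }
  u <- as.vector(u)
  P <- matrix(0, m + 1, n + 1)
  P[seq_len(m), seq_len(n)] <- outer(u, v) * K[seq_len(m), seq_len(n)]
  P[seq_len(m), n + 1] <- u * K[seq_len(m), n + 1]
  P[m + 1, seq_len(n)] <- v * K[m + 1, seq_len(n)]
  P[m + 1, n + 1] <- 1
  P
}

# Random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Longest increasing subsequence of j over pairs sorted by i: the size of the
# best order-preserving sub-alignment of a pair set.
lis_length <- function(pairs) {
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  js <- pairs[, 2]
  tails <- integer(0)
  for (j in js) {
    pos <- findInterval(j - 1L, tails) + 1L
    if (pos > length(tails)) tails <- c(tails, j) else tails[pos] <- j
  }
  length(tails)
}

pair_keys <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = ":")

# total interior similarity of an inferred alignment
inferred_total <- function(coupling, sim, direction = "row") {
  a <- infer_alignment(coupling, direction)
  if (nrow(a$pairs)) sum(sim$S[a$pairs]) else 0
}

# hand-rolled PDB ATOM line with exact fixed columns (independent of
# write_ca_pdb)
pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                     altloc = " ", icode = " ", record = "ATOM  ") {
  sprintf("%s%5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          record, serial, paste0(" ", name), altloc, resname, chain,
          resno, icode, x, y, z)
}
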