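test_that("sinkhorn_partial resolves the 1x1 closed-form case and symmetric ties", {
  sim <- similarity_matrix(matrix(1, 1, 1))
  cp <- sinkhorn_partial(build_cost_matrix(sim), solver_params())
  expect_gt(cp$P[1, 1], 0.99)
  expect_equal(cp$P[2, 2], 1)

  # equal interior costs, equal gap costs: symmetry forces uniform rows
  sim2 <- similarity_matrix(matrix(0.5, 2, 3), gap_col = 0.5, gap_row = 0.5)
  cp2 <- sinkhorn_partial(build_cost_matrix(sim2), solver_params(lambda = 10))
  for (i in 1:2) {
    expect_lt(diff(range(cp2$P[i, 1:3])), 1e-6)
  }
})

test_that("sinkhorn_partial matches an independent probability-domain solver", {
  set.seed(41)
  for (lam in c(10, 100)) {
    sim <- similarity_matrix(matrix(runif(20), 5, 4), gap_col = 0.1, gap_row = 0.1)
    cost <- build_cost_matrix(sim, 0.5)
    cp <- sinkhorn_partial(cost, solver_params(lambda = lam, tmax = 200000))
    P_ref <- plain_sinkhorn(cost$C, 5, 4, lam)
    expect_lt(max(abs(cp$P - P_ref)), 1e-5)
  }
})

test_that("converged couplings are feasible: unit margins, entries in [0,1], corner 1", {
  set.seed(42)
  for (rep_ in 1:25) {
    m <- sample(2:9, 1)
    n <- sample(2:9, 1)
    sim <- similarity_matrix(matrix(runif(m * n), m, n),
                             gap_col = runif(1, 0, 0.3), gap_row = runif(1, 0, 0.3))
    cp <- sinkhorn_partial(build_cost_matrix(sim), solver_params(lambda = 20))
    expect_true(cp$converged)
    expect_true(all(cp$P >= 0 & cp$P <= 1 + 1e-12))
    expect_lt(max(abs(rowSums(cp$P)[1:m] - 1)), 1e-6)
    expect_lt(max(abs(colSums(cp$P)[1:n] - 1)), 1e-6)
    expect_identical(cp$P[m + 1, n + 1], 1)
  }
})

test_that("infer_alignment applies argmax, gap dropping and conflict elimination", {
  # near-identity interior: permutation recovered in full
  P <- diag(0.9, 4)
  P <- rbind(cbind(P, 0.1), c(rep(0.1, 4), 1))
  cp <- structure(list(P = P, m = 4L, n = 4L), class = "coupling")
  a <- infer_alignment(cp, "row")
  expect_equal(a$pairs, cbind(i = 1:4, j = 1:4), ignore_attr = TRUE)

  # rows 1 and 2 both argmax column 2: larger mass wins, loser unaligned
  P2 <- matrix(0.01, 4, 4)
  P2[1, 2] <- 0.6
  P2[2, 2] <- 0.5
  P2[3, 1] <- 0.7
  P2[4, 4] <- 1
  cp2 <- structure(list(P = P2, m = 3L, n = 3L), class = "coupling")
  a2 <- infer_alignment(cp2, "row")
  expect_true(all(pair_keys(cbind(1, 2)) %in% pair_keys(a2$pairs)))
  expect_false(2 %in% a2$pairs[, 1])

  # a row whose mass sits on the gap column is absent
  P3 <- matrix(0.01, 3, 3)
  P3[1, 1] <- 0.9
  P3[2, 3] <- 0.9   # gap column for n = 2
  P3[3, 3] <- 1
  cp3 <- structure(list(P = P3, m = 2L, n = 2L), class = "coupling")
  a3 <- infer_alignment(cp3, "row")
  expect_false(2 %in% a3$pairs[, 1])

  # column direction is the transpose-symmetric rule
  a4 <- infer_alignment(cp2, "col")
  expect_true(all(a4$pairs[, 2] %in% 1:3))
  expect_false(anyDuplicated(a4$pairs[, 1]) > 0)
})

test_that("select_direction picks the higher TM-score and defaults to row on ties", {
  h <- make_helix_chain(20)
  sup <- superposition()
  full <- alignment_result(cbind(1:20, 1:20), "col")
  sub <- alignment_result(cbind(1:10, 1:10), "row")
  # col strictly contains row with zero distances: col must win
  pick <- select_direction(sub, full, h, h, sup)
  expect_equal(pick$direction, "col")
  expect_equal(pick$tm, 1.0)
  # identical alignments: tie resolved to row
  same <- alignment_result(cbind(1:20, 1:20), "row")
  pick2 <- select_direction(same, full, h, h, sup)
  expect_equal(pick2$direction, "row")
  # both empty: row, tm 0
  e1 <- alignment_result(matrix(integer(0), 0, 2), "row")
  e2 <- alignment_result(matrix(integer(0), 0, 2), "col")
  pick3 <- select_direction(e1, e2, h, h, sup)
  expect_equal(pick3$direction, "row")
  expect_equal(pick3$tm, 0)
})

test_that("exact_plsap solves the letter toy and degenerate cases", {
  sim <- letter_problem("abedn", "ACDNB")
  res <- exact_plsap(sim)
  expect_setequal(pair_keys(res$pairs),
                  pair_keys(cbind(c(1, 2, 4, 5), c(1, 5, 3, 4))))
  expect_equal(res$total_similarity, 4)
  expect_false(3 %in% res$pairs[, 1])  # 'e' unaligned
  expect_false(2 %in% res$pairs[, 2])  # 'C' unaligned

  zero <- similarity_matrix(matrix(0, 3, 3))
  expect_equal(exact_plsap(zero)$total_similarity, 0)

  # tie between empty and a zero-score singleton: tie-break keeps it empty
  xy <- letter_problem("x", "Y")
  expect_equal(nrow(exact_plsap(xy)$pairs), 0L)

  # injectivity when one side repeats a letter
  aa <- letter_problem("aa", "A")
  raa <- exact_plsap(aa)
  expect_equal(nrow(raa$pairs), 1L)
  expect_equal(raa$total_similarity, 1)
})

test_that("exact_plsap equals exhaustive enumeration on seeded instances", {
  set.seed(43)
  dims <- list(c(3, 3), c(3, 4), c(4, 4))
  for (rep_ in 1:60) {
    d <- dims[[(rep_ %% 3) + 1]]
    gap <- if (rep_ %% 2 == 0) 0 else runif(1, 0, 0.3)
    sim <- similarity_matrix(matrix(runif(prod(d)), d[1], d[2]),
                             gap_col = gap, gap_row = gap)
    expect_equal(attr(exact_plsap(sim), "objective"),
                 enumerate_plsap_total(sim), tolerance = 1e-9)
  }
})

test_that("entropic solutions approach the exact assignment as lambda grows", {
  set.seed(44)
  agree <- 0
  for (rep_ in 1:20) {
    m <- sample(3:10, 1)
    n <- sample(3:10, 1)
    sim <- similarity_matrix(matrix(runif(m * n), m, n))
    cost <- build_cost_matrix(sim)
    ex <- exact_plsap(sim)
    tots <- vapply(c(50, 200, 800), function(l) {
      cp <- sinkhorn_partial(cost, solver_params(lambda = l, tmax = max(5000, 50 * l)))
      inferred_total(cp, sim)
    }, numeric(1))
    if (abs(tots[3] - ex$total_similarity) < 1e-3) agree <- agree + 1
  }
  expect_gte(agree, 19)
})

test_that("eLSAP ablation fully covers the shorter chain before elimination", {
  set.seed(45)
  for (dims in list(c(4, 7), c(7, 4), c(5, 5))) {
    m <- dims[1]
    n <- dims[2]
    sim <- similarity_matrix(matrix(runif(m * n), m, n))
    cp <- sinkhorn_partial(build_cost_matrix(sim),
                           solver_params(lambda = 100, gap_modeling = FALSE))
    expect_false(cp$gap_modeling)
    if (m <= n) {
      # every query row's argmax is a real column (no gap mass exists)
      sel <- apply(cp$P[1:m, , drop = FALSE], 1, which.max)
      expect_true(all(sel <= n))
      expect_lt(max(abs(rowSums(cp$P)[1:m] - 1)), 1e-6)
    } else {
      sel <- apply(cp$P[, 1:n, drop = FALSE], 2, which.max)
      expect_true(all(sel <= m))
      expect_lt(max(abs(colSums(cp$P)[1:n] - 1)), 1e-6)
    }
  }
})

test_that("gap score monotonically suppresses coverage", {
  h <- make_helix_chain(30)
  gt <- rearrange_segments(h, "circular", cut = 16, noise_sigma = 0.5, seed = 3)
  nali <- vapply(c(0, 0.1, 0.2, 0.4, 0.8), function(g) {
    aln <- solve_from_superposition(gt$query, gt$target, superposition(),
                                    gap_score = g)
    nrow(aln$pairs)
  }, numeric(1))
  expect_true(all(diff(nali) <= 0))
})

test_that("solve_from_superposition handles self-alignment and hopeless inputs", {
  h <- make_helix_chain(25)
  aln <- solve_from_superposition(h, h, superposition())
  expect_equal(aln$pairs[, 1], aln$pairs[, 2])
  expect_equal(nrow(aln$pairs), 25L)
  expect_equal(max(aln$distances), 0)

  # translated 50 Angstrom beyond the cutoff: empty or near-empty
  far <- chain_structure("B", h$resno, h$icode, h$aa, sweep(h$xyz, 2, c(50, 0, 0), "+"))
  aln2 <- solve_from_superposition(h, far, superposition())
  expect_equal(nrow(aln2$pairs), 0L)
  expect_equal(aln2$sp, 0)
})
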