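test_that("read_ca_structure parses CA records, skips altlocs and non-CA residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    SYNTHETIC TEST STRUCTURE",
    pdb_atom(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom(2, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0),
    pdb_atom(3, "CA", "GLY", "A", 2, 4.5, 5.5, 6.5, altloc = "A"),
    pdb_atom(4, "CA", "GLY", "A", 2, 9.9, 9.9, 9.9, altloc = "B"),
    pdb_atom(5, "N",  "SER", "A", 3, 0.0, 0.0, 0.0),  # no CA: skipped
    pdb_atom(6, "CA", "MSE", "A", 4, 7.0, 8.0, 9.0, record = "HETATM"),
    "END"), path)
  ch <- read_ca_structure(path)
  expect_s3_class(ch, "chain_structure")
  expect_equal(length(ch), 3L)
  expect_equal(ch$resno, c(1L, 2L, 4L))
  expect_equal(ch$aa, c("A", "G", "M"))
  expect_equal(ch$xyz[2, ], c(4.5, 5.5, 6.5))  # first altloc wins
})

test_that("read_ca_structure errors on absent chains and empty files", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom(1, "CA", "ALA", "A", 1, 1, 2, 3), "END"), path)
  expect_error(read_ca_structure(path, chain_id = "Z"), "chain 'Z' not found")
  expect_error(read_ca_structure(tempfile()), "not found")
  writeLines("HEADER    EMPTY", path)
  expect_error(read_ca_structure(path), "no ATOM records")
})

test_that("only the first model is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_atom(1, "CA", "ALA", "A", 1, 1, 1, 1),
    "ENDMDL",
    "MODEL        2",
    pdb_atom(1, "CA", "ALA", "A", 1, 9, 9, 9),
    "ENDMDL",
    "END"), path)
  ch <- read_ca_structure(path)
  expect_equal(length(ch), 1L)
  expect_equal(ch$xyz[1, ], c(1, 1, 1))
})

test_that("structure coordinates round-trip through PDB at 3-decimal precision", {
  set.seed(11)
  ch <- chain_structure("B", 1:7, rep("", 7), rep("K", 7),
                        matrix(round(rnorm(21, sd = 20), 3), 7, 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(ch, path)
  back <- read_ca_structure(path, "B")
  expect_equal(back$xyz, ch$xyz, tolerance = 1e-12)
  expect_equal(back$resno, ch$resno)
})

test_that("superposition matrix round-trips for 100 seeded random rotations", {
  path <- withr::local_tempfile(fileext = ".txt")
  set.seed(5)
  for (k in 1:100) {
    sup <- superposition(random_rotation(), rnorm(3, sd = 10))
    write_superposition_matrix(sup, path)
    back <- read_superposition_matrix(path, tol = 1e-9)
    expect_lt(max(abs(back$rotation - sup$rotation)), 1e-9)
    expect_lt(max(abs(back$translation - sup$translation)), 1e-9)
  }
})

test_that("superposition matrix reader handles identity, comments and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("-------- header to ignore --------",
               "i  t(i)  u(i,1) u(i,2) u(i,3)",
               "0  0  1 0 0",
               "1  0  0 1 0",
               "2  0  0 0 1"), path)
  sup <- read_superposition_matrix(path)
  expect_equal(sup$rotation, diag(3))
  expect_equal(sup$translation, c(0, 0, 0))

  writeLines(c("0 0 1 0 0", "1 0 0 1 0"), path)
  expect_error(read_superposition_matrix(path), "fewer than 3")

  writeLines(c("0 0 1 0 0", "1 0 0 1 0", "2 0 0 0 -1"), path)
  expect_error(read_superposition_matrix(path), "reflection")

  # translation lands in the second column
  writeLines(c("0 1 1 0 0", "1 2 0 1 0", "2 3 0 0 1"), path)
  expect_equal(read_superposition_matrix(path)$translation, c(1, 2, 3))
})

test_that("alignment report carries header plus per-pair map rows", {
  h <- make_helix_chain(5)
  path <- withr::local_tempfile(fileext = ".txt")

  empty <- alignment_result(matrix(integer(0), 0, 2), "row",
                            total_similarity = 0, tm = 0, sp = 0)
  write_alignment_report(empty, h, h, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# Nali: 0$", lines)))
  expect_equal(sum(!grepl("^#", lines)), 0L)

  self <- alignment_result(cbind(1:5, 1:5), "row", distances = rep(0, 5),
                           total_similarity = 4, tm = 1, sp = 1)
  write_alignment_report(self, h, h, path)
  lines <- readLines(path)
  rows <- lines[!grepl("^#", lines)]
  expect_length(rows, 5L)
  expect_true(all(grepl("\t0\\.000$", rows)))

  bad <- alignment_result(cbind(1L, 9L), "row", distances = 0)
  expect_error(write_alignment_report(bad, h, h, path), "out of range")
})
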