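test_that("read_pdb parses a toy file into chains, residues, atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, toy_pdb_lines)
  a <- read_pdb(f)
  expect_equal(nrow(a), 4)
  expect_equal(unique(a$chain), "A")
  expect_equal(nrow(residues(a)), 1)
  expect_equal(a$atom, c("N", "CA", "C", "O"))
  expect_equal(a$x[1], 11.104)
  expect_equal(a$polymer, rep("protein", 4))
})

test_that("only the first MODEL of a multi-model file is read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  model2 <- c(
    "MODEL        2",
    "ATOM      9  CA  GLY A   9      99.000  99.000  99.000  1.00  0.00           C",
    "ENDMDL"
  )
  write_mini_pdb(f, c("MODEL        1", toy_pdb_lines[1:4], "ENDMDL",
                      model2, "END"))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f1, toy_pdb_lines)
  a <- read_pdb(f)
  b <- read_pdb(f1)
  expect_equal(coords(a), coords(b))
  expect_equal(nrow(a), 4)
})

test_that("altlocs collapse to the highest-occupancy location", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "END"
  ))
  a <- read_pdb(f)
  expect_equal(nrow(a), 1)
  expect_equal(a$x, 1.0)     # occupancy 0.60 wins
  expect_equal(a$altloc, "A")

  # occupancy tie: lexicographically smallest altloc wins
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f2, c(
    "ATOM      1  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "END"
  ))
  expect_equal(read_pdb(f2)$altloc, "A")
})

test_that("waters are dropped and hydrogens retained but non-heavy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(
    toy_pdb_lines[1:4],
    "ATOM      5  HA  ALA A   1      11.000   6.000  -5.000  1.00  0.00           H",
    "HETATM    6  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ))
  a <- read_pdb(f)
  expect_equal(nrow(a), 5)                       # water gone, H kept
  expect_false(any(a$resn == "HOH"))
  expect_equal(nrow(select_atoms(a, "heavy")), 4)
})

test_that("malformed and empty files raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(toy_pdb_lines[1], "ATOM      2  CA  ALA A   2    bad"))
  expect_error(read_pdb(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f2, c("REMARK nothing here", "END"))
  expect_error(read_pdb(f2), "no ATOM/HETATM")
})

test_that("element is inferred from the atom name when blank", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   ALA A   1       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3 1HB  ALA A   1       3.000   0.000   0.000  1.00  0.00",
    "END"
  ))
  a <- read_pdb(f)
  expect_equal(a$element, c("C", "N", "H"))
})

test_that("write_pdb round-trips coordinates to 3 decimals with TER per chain", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, toy_pdb_lines)
  a <- read_pdb(f)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(a, out)
  b <- read_pdb(out)
  expect_equal(nrow(b), nrow(a))
  expect_equal(b$atom, a$atom)
  expect_equal(coords(b), coords(a), tolerance = 1e-8)

  two <- dplyr::bind_rows(mk_residue(c(0, 0, 0), chain = "A"),
                          mk_residue(c(10, 0, 0), chain = "B", resi = 2L))
  out2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(two, out2)
  txt <- readLines(out2)
  expect_equal(sum(txt == "TER"), 2)
  # each TER directly follows its chain block
  expect_equal(substr(txt[which(txt == "TER") - 1], 22, 22), c("A", "B"))
})

test_that("write_pdb rejects format-breaking values", {
  a <- mk_residue(c(0, 0, 0))
  a$x[1] <- 1234.5678 * 10
  expect_error(write_pdb(a, withr::local_tempfile()), "fixed-width")
  b <- mk_residue(c(0, 0, 0), chain = "AB")
  expect_error(write_pdb(b, withr::local_tempfile()), "single-character")
})

test_that("random assemblies round-trip atom count, ids, and coordinates", {
  withr::local_seed(11)
  for (rep in 1:5) {
    n_res <- sample(3:20, 1)
    asm <- dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
      mk_residue(stats::runif(3, -50, 50), chain = sample(c("A", "B"), 1),
                 resi = i)
    }))
    asm <- asm[order(asm$chain), ]
    asm$serial <- seq_len(nrow(asm))
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(asm, f)
    back <- read_pdb(f)
    expect_equal(nrow(back), nrow(asm))
    expect_equal(back[, c("chain", "resi", "resn", "atom")],
                 asm[, c("chain", "resi", "resn", "atom")],
                 ignore_attr = TRUE)
    expect_equal(coords(back), coords(asm), tolerance = 1e-3)
  }
})

test_that("selection language handles chains, ranges, classes, and 'and'", {
  asm <- dplyr::bind_rows(
    mk_residue(c(0, 0, 0), chain = "A", resi = 1L),
    mk_residue(c(5, 0, 0), chain = "A", resi = 2L),
    mk_residue(c(0, 8, 0), chain = "B", resi = 3L)
  )
  expect_equal(nrow(select_atoms(asm, "chain A")), 10)
  expect_equal(nrow(select_atoms(asm, "resi 2-3")), 10)
  expect_equal(nrow(select_atoms(asm, "chain A and resi 2")), 5)
  expect_equal(select_atoms(asm, "backbone")$atom,
               rep(c("N", "CA", "C", "O"), 3))
  expect_error(select_atoms(asm, "chain Q"), "available")
  expect_error(select_atoms(asm, "nonsense"), "unknown selection")
})

test_that("heavy excludes H/D; backbone is polymer-type aware", {
  res <- mk_residue(c(0, 0, 0))
  h <- mk_atoms(rbind(c(1, 1, 1), c(2, 2, 2)), atom = c("HA", "HB1"),
                element = "H")
  res_h <- dplyr::bind_rows(res, h)
  expect_equal(nrow(select_atoms(res_h, "heavy")), 5)
  expect_equal(select_atoms(res, "backbone")$atom, c("N", "CA", "C", "O"))

  rna <- mk_atoms(matrix(stats::runif(27), 9, 3),
                  atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'",
                           "O3'", "N1"),
                  element = c("P", "O", "O", "O", "C", "C", "C", "O", "N"),
                  resn = "A", polymer = "rna")
  expect_equal(nrow(select_atoms(rna, "backbone")), 8)  # base N1 excluded
  expect_equal(nrow(select_atoms(rna, "nucleic")), 9)
})

test_that("selection is idempotent and class counts are nested", {
  withr::local_seed(5)
  asm <- dplyr::bind_rows(lapply(1:6, function(i) {
    mk_residue(stats::runif(3, -20, 20), resi = i)
  }))
  heavy <- select_atoms(asm, "heavy")
  expect_equal(select_atoms(heavy, "heavy"), heavy, ignore_attr = TRUE)
  expect_lte(nrow(select_atoms(asm, "backbone")), nrow(heavy))
  expect_lte(nrow(heavy), nrow(asm))
})
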