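AA_order <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

write_fasta <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
}

write_clustal <- function(path, seqs) {
  # two blocks, as clustalw emits for longer alignments
  w <- nchar(seqs[1])
  h <- ceiling(w / 2)
  block <- function(sub) {
    c(paste0(formatC(names(seqs), width = -16), sub),
      paste0(strrep(" ", 16), strrep(" ", nchar(sub[1]))), "")
  }
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               block(substr(seqs, 1, h)),
               block(substr(seqs, h + 1, w))), path)
}

test_that("fasta and clustal readers agree and validate the alphabet", {
  seqs <- c(s1 = "ACDE-", s2 = "ACDEF", s3 = "acd-f")
  f1 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(f1, seqs)
  m1 <- read_alignment(f1, "fasta")
  expect_equal(nrow(m1), 3)
  expect_equal(m1$sequence[3], "ACD-F")     # uppercased

  f2 <- withr::local_tempfile(fileext = ".aln")
  write_clustal(f2, toupper(seqs))
  m2 <- read_alignment(f2, "clustal")
  expect_equal(m2$sequence, m1$sequence)

  expect_error(msa(c(a = "ACD", b = "AC")), "ragged.*'b'")
  expect_error(msa(c(a = "ACD", b = "A2D")), "invalid characters.*'b'")
})

test_that("conservation hits the closed-form anchors", {
  # all-K column scores exactly 1; uniform 20-letter column scores 0
  rows <- vapply(1:20, function(i) paste0("K", AA_order()[i]), character(1))
  m <- msa(setNames(rows, paste0("s", 1:20)))
  prof <- conservation_profile(m)
  expect_equal(prof$score[1], 1.0)
  expect_equal(prof$score[2], 0.0, tolerance = 1e-9)

  # half K / half R: frozen value from an independent closed-form
  # computation of JSD({K:.5,R:.5} || uniform20) / JSD(point mass || uniform20)
  half <- msa(setNames(c(rep("K", 5), rep("R", 5)), paste0("s", 1:10)))
  prof2 <- conservation_profile(half)
  expect_equal(prof2$score, 0.8868759796967592, tolerance = 1e-9)
})

test_that("gap handling penalizes and flags columns", {
  m <- msa(c(a = "K-", b = "K-", c = "K-", d = "K-"))
  expect_warning(prof <- conservation_profile(m), "all-gap")
  expect_equal(prof$score[2], 0)
  expect_true(prof$all_gap[2])
  # gap fraction scales the score: half-gapped invariant column
  m2 <- msa(c(a = "K", b = "K", c = "-", d = "-"))
  expect_equal(conservation_profile(m2)$score, 0.5)
})

test_that("conservation is invariant to row order; consensus duplication never hurts", {
  toy <- make_toy_msa(toy_msa_spec(seed = 2, n_rows = 8, n_columns = 30,
                                   planted_columns = c(3, 11),
                                   gap_rate = 0))
  m <- toy$msa
  p1 <- conservation_profile(m)
  shuffled <- m[rev(seq_len(nrow(m))), ]
  p2 <- conservation_profile(shuffled)
  expect_equal(p1$score, p2$score)

  # duplicating the per-column consensus letters never decreases a score
  mm <- do.call(rbind, strsplit(m$sequence, ""))
  consensus <- apply(mm, 2, function(col) {
    names(sort(table(col), decreasing = TRUE))[1]
  })
  dup <- msa(setNames(c(m$sequence, paste(consensus, collapse = "")),
                      c(m$id, "consensus")))
  p3 <- conservation_profile(dup)
  expect_true(all(p3$score >= p1$score - 1e-12))

  # duplicating an arbitrary row perturbs each column only slightly
  dup2 <- msa(setNames(c(m$sequence, m$sequence[2]), c(m$id, "dup")))
  p4 <- conservation_profile(dup2)
  expect_lt(max(abs(p4$score - p1$score)), 0.05)
})

test_that("categories bin at documented tier boundaries", {
  expect_equal(categorize_conservation(c(1.0, 0.8, 0.79, 0.5, 0.49, 0)),
               c("high", "high", "moderate", "moderate", "low", "low"))
  prof <- conservation_profile(msa(c(a = "KK", b = "KR")))
  expect_equal(prof$category,
               categorize_conservation(prof$score))
})

test_that("column maps follow the k-th non-gap rule and report mismatches", {
  chain_res <- tibble::tibble(chain = "K", resi = 7:10, icode = "",
                              resn = c("ALA", "CYS", "ASP", "GLU"),
                              polymer = "protein", n_atoms = 5L)
  m <- msa(c(ref = "AC-DE", other = "ACQDE"))
  cm <- map_columns_to_residues(m, "ref", chain_res)
  expect_equal(cm$column, c(1, 2, 4, 5))
  expect_equal(cm$resi, 7:10)
  expect_true(all(cm$matches))

  expect_error(map_columns_to_residues(msa(c(ref = "---", o = "ACD")),
                                       "ref", chain_res), "all gaps")
  expect_error(map_columns_to_residues(m, "ref", chain_res[1:2, ]),
               "2 residues")

  # 43 leading reference gaps: alignment column 120 maps to residue 77
  lead <- strrep("-", 43)
  ref <- paste0(lead, strrep("A", 120 - 43))
  other <- strrep("A", 120)
  chain2 <- tibble::tibble(chain = "K", resi = seq_len(77), icode = "",
                           resn = "ALA", polymer = "protein", n_atoms = 5L)
  cm2 <- map_columns_to_residues(msa(c(ref = ref, o = other)), "ref", chain2)
  expect_equal(cm2$resi[cm2$column == 120], 77)
  expect_equal(max(cm2$column), 120)

  # mismatching identity letters are reported, not dropped
  chain3 <- dplyr::mutate(chain_res, resn = c("ALA", "CYS", "TRP", "GLU"))
  cm3 <- map_columns_to_residues(m, "ref", chain3)
  expect_equal(sum(!cm3$matches), 1)
  expect_equal(attr(cm3, "mismatches")$resi, 9)
})

test_that("top_conserved recovers planted columns and breaks ties earliest-first", {
  toy <- make_toy_msa(toy_msa_spec(seed = 6, n_rows = 12, n_columns = 40,
                                   planted_columns = c(5, 20, 33)))
  prof <- conservation_profile(toy$msa)
  chain_res <- tibble::tibble(chain = "K", resi = 1:40, icode = "",
                              resn = "ALA", polymer = "protein",
                              n_atoms = 5L)
  cm <- map_columns_to_residues(toy$msa, "ref", chain_res)
  top <- top_conserved(prof, cm, 3)
  expect_setequal(top$column, c(5, 20, 33))

  # k = column count returns all mapped residues
  expect_equal(nrow(top_conserved(prof, cm, 40)), 40)

  # tie at the max: earlier column wins
  m <- msa(c(ref = "KAKA", a = "KCKC", b = "KDKD"))
  p <- conservation_profile(m)
  res4 <- tibble::tibble(chain = "K", resi = 1:4, icode = "", resn = "ALA",
                         polymer = "protein", n_atoms = 5L)
  cmap <- map_columns_to_residues(m, "ref", res4)
  expect_equal(top_conserved(p, cmap, 1)$column, 1)
})

test_that("toy MSA generator plants exactly what it claims", {
  spec <- toy_msa_spec(seed = 10, n_rows = 10, n_columns = 50,
                       planted_columns = c(5, 20, 33), gap_rate = 0.1)
  toy <- make_toy_msa(spec)
  mm <- do.call(rbind, strsplit(toy$msa$sequence, ""))
  for (j in toy$truth$planted_columns) {
    expect_equal(length(unique(mm[, j])), 1)
    expect_false("-" %in% mm[, j])
  }
  # gap-free when gap_rate is 0
  toy0 <- make_toy_msa(toy_msa_spec(seed = 10, gap_rate = 0))
  expect_false(grepl("-", paste(toy0$msa$sequence, collapse = "")))
  # same planted columns across seeds, different noise
  t1 <- make_toy_msa(toy_msa_spec(seed = 1))
  t2 <- make_toy_msa(toy_msa_spec(seed = 2))
  expect_false(identical(t1$msa$sequence, t2$msa$sequence))
})

AA_order <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
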