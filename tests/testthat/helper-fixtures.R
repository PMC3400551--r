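# Builders and independent oracles shared across the suite.

# minimal atom table from an n-by-3 coordinate matrix; vectors recycle
mk_atoms <- function(xyz, chain = "A", resi = 1L, atom = "CA",
                     element = "C", resn = "ALA", polymer = "protein",
                     hetero = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    chain = rep_len(chain, n), resi = as.integer(rep_len(resi, n)),
    icode = "", resn = rep_len(resn, n),
    polymer = rep_len(polymer, n), serial = seq_len(n),
    atom = rep_len(atom, n), altloc = "",
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    hetero = rep_len(hetero, n)
  )
}

# one protein residue with a standard backbone + CB
mk_residue <- function(origin, chain = "A", resi = 1L, resn = "ALA") {
  offs <- rbind(N = c(-1.2, 0.5, -0.6), CA = c(0, 0, 0),
                C = c(1.3, 0.4, 0.5), O = c(1.6, 1.55, 0.7),
                CB = c(-0.4, -1.4, 0.55))
  mk_atoms(sweep(offs, 2, -origin), chain = chain, resi = resi,
           atom = rownames(offs), element = c("N", "C", "C", "O", "C"),
           resn = resn)
}

# random CA-only pseudo-protein for oracle comparisons
rand_atoms <- function(n, chain = "A", spread = 20, seed_offset = 0) {
  xyz <- matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
  mk_atoms(xyz, chain = chain, resi = seq_len(n))
}

# --- independent brute-force oracles -----------------------------------

bf_dist_matrix <- function(a, b) {
  ca <- if (is.matrix(a)) a else ribosite::coords(a)
  cb <- if (is.matrix(b)) b else ribosite::coords(b)
  out <- matrix(0, nrow(ca), nrow(cb))
  for (i in seq_len(nrow(ca))) {      # exhaustive double loop on purpose
    for (j in seq_len(nrow(cb))) {
      out[i, j] <- sqrt(sum((ca[i, ] - cb[j, ])^2))
    }
  }
  out
}

bf_pairs_within <- function(a, b, cutoff) {
  d <- bf_dist_matrix(a, b)
  idx <- which(d < cutoff, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], dist = d[idx])
  out[order(out$dist, out$i, out$j), , drop = FALSE]
}

bf_min_dist <- function(a, b) min(bf_dist_matrix(a, b))

# Monte-Carlo SASA oracle: uniform random sphere directions (seeded),
# independent of the deterministic golden-spiral implementation path
mc_sasa <- function(xyz, radii, probe = 1.4, n_points = 20000, seed = 99) {
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    n <- nrow(xyz)
    vapply(seq_len(n), function(i) {
      ri <- radii[i] + probe
      pts <- sweep(v * ri, 2, xyz[i, ], `+`)
      exposed <- rep(TRUE, n_points)
      for (j in seq_len(n)[-i]) {
        rj <- radii[j] + probe
        dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
        exposed <- exposed & (dj >= rj)
      }
      4 * pi * ri^2 * mean(exposed)
    }, numeric(1))
  })
}

write_mini_pdb <- function(path, lines) writeLines(lines, path)

# a 4-atom single-residue toy PDB, coordinates chosen in the test
toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      12.685   7.205  -5.033  1.00  0.00           C",
  "ATOM      4  O   ALA A   1      12.512   8.300  -5.595  1.00  0.00           O",
  "END"
)
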