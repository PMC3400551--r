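# small two-chain assembly with a well-separated anchor chain "K";
# CA positions follow a helix so they are never collinear (a collinear
# anchor would leave the superposition rotation under-determined)
make_mini_assembly <- function() {
  k <- dplyr::bind_rows(lapply(1:6, function(i) {
    mk_residue(c(2 * cos(1.7 * i), 2 * sin(1.7 * i), 3 * i),
               chain = "K", resi = i)
  }))
  b <- dplyr::bind_rows(lapply(1:6, function(i) {
    mk_residue(c(14 + 2 * cos(1.7 * i), 2 * sin(1.7 * i), 3 * i),
               chain = "B", resi = i + 10L)
  }))
  out <- dplyr::bind_rows(k, b)
  out$serial <- seq_len(nrow(out))
  out
}

test_that("anchor_superpose recovers identity and pre-applied transforms", {
  asm <- make_mini_assembly()
  anchor <- dplyr::filter(asm, chain == "K")
  s <- anchor_superpose(anchor, asm, "K")
  expect_lt(s$rmsd, 1e-6)
  expect_equal(s$transform$rotation, diag(3), tolerance = 1e-6)
  expect_equal(s$n_atoms, 6)

  th <- 0.6
  r <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  tf <- rigid_transform(r, c(5, -2, 8))
  moved <- apply_transform(anchor, tf)
  s2 <- anchor_superpose(moved, asm, "K")
  expect_lt(s2$rmsd, 1e-6)
  expect_equal(s2$transform$rotation, t(r), tolerance = 1e-6)
})

test_that("anchor_superpose matches by author residue number", {
  asm <- make_mini_assembly()
  anchor <- dplyr::filter(asm, chain == "K")
  # renumber 2 residues out of the match
  renum <- anchor
  renum$resi[renum$resi %in% c(5, 6)] <- c(105L, 106L)[
    match(renum$resi[renum$resi %in% c(5, 6)], c(5, 6))]
  s <- anchor_superpose(renum, asm, "K")
  expect_equal(s$n_atoms, 4)   # 6 residues minus the 2 renumbered
  expect_lt(s$rmsd, 1e-6)

  few <- dplyr::filter(anchor, resi <= 2)
  expect_error(anchor_superpose(few, asm, "K"), "fewer than 3")
  expect_error(anchor_superpose(anchor, asm, "Q"), "not in assembly")
})

test_that("place_pose is rigid and composes transforms correctly", {
  lig <- dplyr::bind_rows(mk_residue(c(0, 0, 0), chain = "Z", resi = 1L),
                          mk_residue(c(4, 0, 0), chain = "Z", resi = 2L))
  ident <- rigid_transform()
  expect_equal(coords(place_pose(ident, lig, ident)), coords(lig))

  withr::local_seed(14)
  th <- 1.3
  r1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  pose <- rigid_transform(r1, c(2, 4, -1))
  th2 <- -0.4
  r2 <- matrix(c(1, 0, 0, 0, cos(th2), -sin(th2), 0, sin(th2), cos(th2)),
               3, 3, byrow = TRUE)
  anchor_tf <- rigid_transform(r2, c(-6, 0, 9))

  placed <- place_pose(pose, lig, anchor_tf)
  # rigidity: intra-ligand distances preserved
  expect_equal(bf_dist_matrix(placed, placed), bf_dist_matrix(lig, lig),
               tolerance = 1e-9)
  # composition equals applying the transforms one after the other
  stepwise <- apply_transform(apply_transform(coords(lig), pose), anchor_tf)
  expect_equal(coords(placed), stepwise, tolerance = 1e-9)
})

test_that("clash_screen applies the strict 2 A backbone rule", {
  ctx <- mk_residue(c(0, 0, 0), chain = "B")
  # ligand CA exactly 1.99 A from the context CA
  lig <- mk_atoms(matrix(c(1.99, 0, 0), 1), chain = "Z", atom = "CA")
  rep1 <- clash_screen(lig, ctx, clash_params())
  expect_gte(rep1$clash_count, 1)

  lig2 <- mk_atoms(matrix(c(2.0, 0, 0), 1), chain = "Z", atom = "CA")
  ctx_far <- mk_atoms(matrix(c(0, 0, 0), 1), chain = "B", atom = "CA")
  rep2 <- clash_screen(lig2, ctx_far, clash_params())
  expect_equal(rep2$clash_count, 0)
  expect_equal(rep2$min_backbone_distance, 2.0)

  # report invariants
  expect_equal(rep1$clash_count, nrow(rep1$pairs))
  expect_true((rep2$clash_count == 0) ==
                (rep2$min_backbone_distance >= 2.0))
})

test_that("clash_screen restricts to backbone atoms and honors exclusions", {
  ctx <- make_mini_assembly()
  # ligand CB 1 A from a context CB: side-chain proximity is not a clash
  cb <- dplyr::filter(ctx, chain == "B", resi == 11, atom == "CB")
  lig <- mk_atoms(rbind(coords(cb) + c(0, -1, 0),
                        coords(cb) + c(30, 0, 0)),
                  chain = "Z", atom = c("CB", "CA"))
  expect_equal(clash_screen(lig, ctx, clash_params())$clash_count, 0)

  # excluding chain B removes its clashes
  ca <- dplyr::filter(ctx, chain == "B", resi == 11, atom == "CA")
  lig2 <- mk_atoms(coords(ca) + c(1, 0, 0), chain = "Z", atom = "CA")
  expect_gte(clash_screen(lig2, ctx, clash_params())$clash_count, 1)
  expect_equal(clash_screen(
    lig2, ctx, clash_params(excluded_chains = "B"))$clash_count, 0)
  expect_error(clash_screen(lig2, dplyr::filter(ctx, chain == "B"),
                            clash_params(excluded_chains = "B")),
               "empty")
})

test_that("clash reports equal an exhaustive double-loop scan", {
  withr::local_seed(23)
  for (rep in 1:5) {
    ctx <- dplyr::bind_rows(lapply(1:12, function(i) {
      mk_residue(stats::runif(3, -12, 12), chain = "B", resi = i)
    }))
    lig <- dplyr::bind_rows(lapply(1:4, function(i) {
      mk_residue(stats::runif(3, -12, 12), chain = "Z", resi = i)
    }))
    got <- clash_screen(lig, ctx, clash_params())
    lig_bb <- dplyr::filter(lig, atom %in% c("N", "CA", "C", "O"))
    ctx_bb <- dplyr::filter(ctx, atom %in% c("N", "CA", "C", "O"))
    want <- bf_pairs_within(lig_bb, ctx_bb, 2.0)
    expect_equal(got$clash_count, nrow(want))
    expect_equal(sort(got$pairs$dist), sort(want$dist), tolerance = 1e-12)
    expect_equal(got$min_backbone_distance, bf_min_dist(lig_bb, ctx_bb),
                 tolerance = 1e-12)
  }
})

test_that("clash count is monotone in the context", {
  withr::local_seed(9)
  ctx <- dplyr::bind_rows(lapply(1:8, function(i) {
    mk_residue(stats::runif(3, -6, 6), chain = "B", resi = i)
  }))
  extra <- dplyr::bind_rows(lapply(1:4, function(i) {
    mk_residue(stats::runif(3, -6, 6), chain = "C", resi = i)
  }))
  lig <- mk_residue(c(0, 0, 0), chain = "Z")
  n1 <- clash_screen(lig, ctx, clash_params())$clash_count
  n2 <- clash_screen(lig, dplyr::bind_rows(ctx, extra),
                     clash_params())$clash_count
  expect_gte(n2, n1)
})

test_that("the first clash-free pose in score order is selected", {
  toy <- make_toy_assembly(toy_assembly_spec(seed = 3,
                                             decoy_clashes = rep(2, 5)))
  fit <- anchor_superpose(toy$receptor, toy$context, "K")
  sel <- select_first_clashfree(toy$poses, toy$ligand, fit, toy$context,
                                anchor_chain = "K")
  expect_true(sel$admissible)
  expect_equal(sel$selected_rank, 6)
  # short-circuit: only poses up to the selected one are screened
  expect_equal(nrow(sel$reports), 6)
  expect_true(all(sel$reports$clash_count[sel$reports$rank < 6] > 0))
  expect_equal(sel$reports$clash_count[sel$reports$rank == 6], 0)

  # appending poses after the selected rank changes nothing
  toy2 <- make_toy_assembly(toy_assembly_spec(seed = 3,
                                              decoy_clashes = rep(2, 5),
                                              n_trailing = 4))
  sel2 <- select_first_clashfree(toy2$poses, toy2$ligand, fit, toy2$context,
                                 anchor_chain = "K")
  expect_equal(sel2$selected_rank, sel$selected_rank)

  # exhaustive mode screens everything
  sel3 <- select_first_clashfree(toy2$poses, toy2$ligand, fit, toy2$context,
                                 anchor_chain = "K", exhaustive = TRUE)
  expect_equal(nrow(sel3$reports), nrow(toy2$poses))
  expect_equal(sel3$selected_rank, sel$selected_rank)
})

test_that("all-clash-free and none-admissible edge cases behave", {
  toy <- make_toy_assembly(toy_assembly_spec(seed = 5,
                                             decoy_clashes = rep(2, 3)))
  fit <- anchor_superpose(toy$receptor, toy$context, "K")
  # keep only the true pose and trailing poses: rank 1 selected
  clashfree <- toy$poses[toy$poses$rank >= toy$truth$true_rank, ]
  clashfree <- rank_poses(clashfree)
  sel <- select_first_clashfree(clashfree, toy$ligand, fit, toy$context,
                                anchor_chain = "K")
  expect_equal(sel$selected_rank, 1)

  # only the planted-clash decoys: none admissible, all reports present
  decoys <- rank_poses(toy$poses[toy$poses$rank < toy$truth$true_rank, ])
  sel2 <- select_first_clashfree(decoys, toy$ligand, fit, toy$context,
                                 anchor_chain = "K")
  expect_false(sel2$admissible)
  expect_true(is.na(sel2$selected_rank))
  expect_equal(nrow(sel2$reports), 3)
  expect_null(sel2$pose)
})

test_that("partner_overlap flags interpenetration and matches clash_screen", {
  lig <- dplyr::bind_rows(lapply(1:3, function(i) {
    mk_residue(c(0, 0, 3 * i), chain = "Z", resi = i)
  }))
  far <- apply_transform(lig, rigid_transform(diag(3), c(100, 0, 0)))
  far$chain <- "S"
  rep_far <- partner_overlap(lig, far)
  expect_equal(rep_far$clash_count, 0)
  expect_false(rep_far$blocked)

  near <- apply_transform(lig, rigid_transform(diag(3), c(0.5, 0, 0)))
  near$chain <- "S"
  rep_near <- partner_overlap(lig, near)
  expect_gt(rep_near$clash_count, 0)
  expect_true(rep_near$blocked)

  # equivalence with clash_screen under no exclusions
  ref <- clash_screen(lig, near, clash_params(excluded_chains = NULL))
  expect_equal(rep_near$clash_count, ref$clash_count)
  expect_equal(rep_near$pairs, ref$pairs)
})
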