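#' Specification for a planted toy assembly
#'
#' Describes a self-contained synthetic system emulating, at toy scale,
#' the geometry of a factor docking onto one protein of a large assembly:
#' several pseudo-helical chains (one of them the anchor), a smaller
#' ligand chain, a planted true pose that touches the anchor and is free
#' of backbone clashes against the rest of the assembly, and score-ranked
#' decoy poses each planted to clash with the context by a known number
#' of backbone-pair violations.
#'
#' Chains are poly-alanine-like (N, CA, C, O, CB) laid on a parametric
#' helix — chemically meaningless but geometrically realistic, which is
#' all the purely distance-based pipeline logic needs.
#'
#' @param n_chains Context chains including the anchor (>= 2).
#' @param residues_per_chain Residues per context chain.
#' @param rise,helix_radius Helix rise per residue and radius, Angstrom.
#' @param anchor_chain Anchor chain id.
#' @param ligand_residues Residues in the ligand chain (id `"Z"`).
#' @param chain_spacing Distance between neighboring chain axes, Angstrom.
#' @param decoy_clashes Integer vector: planted backbone-clash violations
#'   for each decoy pose; decoys occupy ranks `1..length(decoy_clashes)`
#'   and the true pose the next rank.
#' @param n_trailing Additional clash-free, lower-scored poses appended
#'   after the true pose.
#' @param touch_distance Closest heavy-atom approach of the true pose to
#'   the anchor, Angstrom (default 4.0, inside the 4.6 A contact rule).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `toy_assembly_spec`.
#' @export
toy_assembly_spec <- function(n_chains = 4, residues_per_chain = 30,
                              rise = 1.5, helix_radius = 2.3,
                              anchor_chain = "K", ligand_residues = 12,
                              chain_spacing = 16,
                              decoy_clashes = rep(3, 16), n_trailing = 0,
                              touch_distance = 4.0, seed = 1) {
  stopifnot(n_chains >= 2, residues_per_chain >= 3, ligand_residues >= 3,
            all(decoy_clashes >= 1))
  structure(
    list(n_chains = n_chains, residues_per_chain = residues_per_chain,
         rise = rise, helix_radius = helix_radius,
         anchor_chain = anchor_chain, ligand_residues = ligand_residues,
         chain_spacing = chain_spacing, decoy_clashes = decoy_clashes,
         n_trailing = n_trailing, touch_distance = touch_distance,
         seed = seed),
    class = "toy_assembly_spec"
  )
}

# poly-alanine-like residues (N, CA, C, O, CB) along a helix about an
# axis through `origin` in direction `axis_x/axis_y` plane normal z
helix_chain <- function(chain_id, n_res, rise, radius, origin,
                        start_resi = 1) {
  i <- seq_len(n_res)
  theta <- i * 100 * pi / 180
  ca <- cbind(radius * cos(theta) + origin[1],
              radius * sin(theta) + origin[2],
              rise * i + origin[3])
  # fixed local offsets from CA (roughly bond-length scale)
  offs <- list(N = c(-1.20, 0.50, -0.60), C = c(1.30, 0.40, 0.50),
               O = c(1.60, 1.55, 0.70), CB = c(-0.40, -1.40, 0.55))
  atoms <- lapply(i, function(k) {
    base <- ca[k, ]
    tibble::tibble(
      chain = chain_id, resi = as.integer(start_resi + k - 1), icode = "",
      resn = "ALA", polymer = "protein",
      atom = c("N", "CA", "C", "O", "CB"),
      altloc = "", element = c("N", "C", "C", "O", "C"),
      x = base[1] + c(offs$N[1], 0, offs$C[1], offs$O[1], offs$CB[1]),
      y = base[2] + c(offs$N[2], 0, offs$C[2], offs$O[2], offs$CB[2]),
      z = base[3] + c(offs$N[3], 0, offs$C[3], offs$O[3], offs$CB[3]),
      occ = 1, hetero = FALSE
    )
  })
  out <- dplyr::bind_rows(atoms)
  out$serial <- seq_len(nrow(out))
  dplyr::relocate(out, "chain", "resi", "icode", "resn", "polymer", "serial")
}

#' Generate a planted toy assembly with ground truth
#'
#' Builds the context assembly, a docking-frame copy of the anchor chain
#' (the receptor), a ligand, and a ranked pose set in which the decoys of
#' the clash plan occupy the top ranks and the planted true pose is the
#' first clash-free pose. Every fixture is self-certified before being
#' returned: the true pose must screen clash-free against the
#' context-minus-anchor, touch the anchor under the contact cutoff, and
#' each decoy must carry at least its planned number of violations; the
#' true-pose contact pairs recorded in the ground truth are verified
#' against the interface-contact machinery at generation time.
#'
#' @param spec A [toy_assembly_spec()].
#' @return A list of class `toy_assembly`: `context`, `receptor`,
#'   `ligand`, `poses` (ranked `pose_set`), and `truth` — a list with
#'   `true_rank`, `true_transform` (ligand frame to assembly frame),
#'   `decoy_clash_counts`, `contacts` (true-pose/anchor residue contacts),
#'   and `exposure` (per anchor residue, vs the placed true ligand).
#' @export
make_toy_assembly <- function(spec = toy_assembly_spec()) {
  local_seed(spec$seed, {
    nres <- spec$residues_per_chain
    other_ids <- setdiff(c(LETTERS[1:8]), spec$anchor_chain)
    chain_ids <- c(spec$anchor_chain, other_ids[seq_len(spec$n_chains - 1)])
    # anchor on the z axis; other chains fan out on the +x half plane
    angles <- seq(-70, 70, length.out = spec$n_chains - 1) * pi / 180
    origins <- rbind(c(0, 0, 0),
                     cbind(spec$chain_spacing * cos(angles),
                           spec$chain_spacing * sin(angles), 0))
    context <- dplyr::bind_rows(lapply(seq_along(chain_ids), function(i) {
      helix_chain(chain_ids[i], nres, spec$rise, spec$helix_radius,
                  origins[i, ])
    }))
    context$serial <- seq_len(nrow(context))
    context <- new_ribo_atoms(context, id = "toy_context")

    anchor <- dplyr::filter(context, .data$chain == spec$anchor_chain)
    anchor <- new_ribo_atoms(anchor, id = "toy_anchor")

    # ligand built centered at the origin in its own frame
    lig <- helix_chain("Z", spec$ligand_residues, spec$rise,
                       spec$helix_radius, c(0, 0, 0))
    lc <- colMeans(coords(lig))
    lig <- set_coords(lig, sweep(coords(lig), 2, lc))
    lig <- new_ribo_atoms(lig, id = "toy_ligand")

    # true pose: slide the ligand in from -x until first touch with the
    # anchor (the other chains sit on +x, so the pose is clash-free)
    anchor_c <- colMeans(coords(anchor))
    u <- c(-1, 0, 0)
    t_true <- slide_to_touch(coords(select_atoms(anchor, "heavy")),
                             coords(select_atoms(lig, "heavy")),
                             anchor_c, u, 60, spec$touch_distance)
    if (is.na(t_true)) abort("could not plant a touching true pose")
    true_tf <- rigid_transform(diag(3), anchor_c + u * t_true)

    # docking frame: a fixed rotation + offset of the assembly frame
    ang <- 35 * pi / 180
    dock_tf <- rigid_transform(
      matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
             3, 3, byrow = TRUE),
      c(7, -4, 3))
    receptor <- new_ribo_atoms(apply_transform(anchor, dock_tf),
                               id = "toy_receptor")

    # decoys: translate the true pose toward non-anchor chains until the
    # planned number of backbone violations is planted (bisection)
    ctx_minus <- dplyr::filter(context, .data$chain != spec$anchor_chain)
    ctx_bb <- coords(select_atoms(ctx_minus, "backbone"))
    lig_bb_local <- coords(select_atoms(lig, "backbone"))
    n_decoys <- length(spec$decoy_clashes)
    targets <- origins[-1, , drop = FALSE]
    decoy_tfs <- vector("list", n_decoys)
    decoy_counts <- integer(n_decoys)
    for (d in seq_len(n_decoys)) {
      tgt <- targets[((d - 1) %% nrow(targets)) + 1, ] +
        c(0, 0, runif(1, 0.3 * nres * spec$rise, 0.7 * nres * spec$rise))
      dir <- tgt - true_tf$translation
      dir <- dir / sqrt(sum(dir^2))
      nclash <- function(alpha) {
        pos <- true_tf$translation + alpha * dir
        placed <- lig_bb_local +
          matrix(pos, nrow(lig_bb_local), 3, byrow = TRUE)
        nrow(cpp_pairs_within(placed, ctx_bb, 2.0))
      }
      hi <- sqrt(sum((tgt - true_tf$translation)^2))
      if (nclash(hi) < spec$decoy_clashes[d]) {
        abort("unsatisfiable clash plan: decoy cannot reach the context")
      }
      lo <- 0
      while (hi - lo > 0.01) {
        mid <- (lo + hi) / 2
        if (nclash(mid) >= spec$decoy_clashes[d]) hi <- mid else lo <- mid
      }
      decoy_tfs[[d]] <- rigid_transform(diag(3),
                                        true_tf$translation + hi * dir)
      decoy_counts[d] <- nclash(hi)
    }

    # trailing clash-free poses, pushed further out along -x
    trail_tfs <- lapply(seq_len(spec$n_trailing), function(k) {
      rigid_transform(diag(3), true_tf$translation + c(-5 * k, 0, 0))
    })

    # assembly-frame transforms in rank order; pose table stores them in
    # the docking (receptor) frame, as an external engine would
    asm_tfs <- c(decoy_tfs, list(true_tf), trail_tfs)
    rec_tfs <- lapply(asm_tfs, function(tf) compose_transforms(dock_tf, tf))
    n_total <- length(rec_tfs)
    poses <- pose_set(rec_tfs, score = seq(n_total, 1) + 10,
                      source = "internal",
                      receptor_id = "toy_receptor", ligand_id = "toy_ligand")
    poses <- rank_poses(poses)
    true_rank <- n_decoys + 1L

    # ---- self-certification against the pipeline's own screens ----
    anchor_fit <- anchor_superpose(receptor, context, spec$anchor_chain)
    placed_true <- place_pose(pose_transform(poses, true_rank), lig,
                              anchor_fit)
    stopifnot(max(abs(coords(placed_true) -
                        apply_transform(coords(lig), true_tf))) < 1e-6)
    scr <- clash_screen(placed_true, context,
                        clash_params(excluded_chains = spec$anchor_chain))
    if (scr$clash_count != 0) abort("planted true pose clashes with context")
    contacts <- interface_contacts(placed_true, anchor)
    if (nrow(contacts) == 0) abort("planted true pose has no anchor contact")
    for (d in seq_len(n_decoys)) {
      dscr <- clash_screen(place_pose(pose_transform(poses, d), lig,
                                      anchor_fit),
                           context,
                           clash_params(excluded_chains = spec$anchor_chain))
      if (dscr$clash_count < spec$decoy_clashes[d]) {
        abort("planted decoy lost its violations")
      }
      decoy_counts[d] <- dscr$clash_count
    }
    exposure <- suppressWarnings(
      interface_exposure(anchor, placed_true, chain = spec$anchor_chain)
    )

    structure(
      list(context = context, receptor = receptor, ligand = lig,
           poses = poses,
           truth = list(true_rank = true_rank, true_transform = true_tf,
                        decoy_clash_counts = decoy_counts,
                        contacts = contacts, exposure = exposure,
                        anchor_chain = spec$anchor_chain),
           spec = spec),
      class = "toy_assembly"
    )
  })
}

#' Write a toy fixture to standard text formats
#'
#' Emits `context.pdb`, `receptor.pdb`, `ligand.pdb`, `poses.tsv`, and
#' `truth.json` under `dir`. Byte-identical output per seed.
#'
#' @param toy A `toy_assembly` from [make_toy_assembly()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_toy_fixture <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(toy$context, file.path(dir, "context.pdb"))
  write_pdb(toy$receptor, file.path(dir, "receptor.pdb"))
  write_pdb(toy$ligand, file.path(dir, "ligand.pdb"))
  write_poses(toy$poses, file.path(dir, "poses.tsv"))
  truth <- toy$truth
  jsonlite::write_json(
    list(true_rank = truth$true_rank,
         anchor_chain = truth$anchor_chain,
         decoy_clash_counts = truth$decoy_clash_counts,
         contacts = as.data.frame(truth$contacts),
         exposure = as.data.frame(truth$exposure)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Specification for a planted toy alignment
#'
#' @param n_rows,n_columns Alignment dimensions.
#' @param planted_columns Column indices forced invariant (and gap-free)
#'   across all rows.
#' @param background Sampling probabilities over the 20 amino acids for
#'   non-planted positions (default uniform).
#' @param gap_rate Per-cell gap probability in non-reference rows at
#'   non-planted columns.
#' @param reference_row_id Row id of the (gap-free) reference sequence.
#' @param seed Integer seed.
#' @return A list of class `toy_msa_spec`.
#' @export
toy_msa_spec <- function(n_rows = 10, n_columns = 50,
                         planted_columns = c(5, 20, 33),
                         background = NULL, gap_rate = 0.05,
                         reference_row_id = "ref", seed = 1) {
  stopifnot(n_rows >= 2, all(planted_columns <= n_columns),
            gap_rate >= 0, gap_rate < 1)
  structure(
    list(n_rows = n_rows, n_columns = n_columns,
         planted_columns = as.integer(planted_columns),
         background = background %||% rep(1 / 20, 20),
         gap_rate = gap_rate, reference_row_id = reference_row_id,
         seed = seed),
    class = "toy_msa_spec"
  )
}

#' Generate a planted toy alignment with ground truth
#'
#' Non-planted cells are sampled from the background distribution (with
#' gaps at `gap_rate` in non-reference rows); planted columns are
#' invariant and gap-free, so they score exactly 1 under the normalized
#' Jensen-Shannon conservation score. The reference row is gap-free, so
#' column k maps to the k-th residue of a matching chain.
#'
#' @param spec A [toy_msa_spec()].
#' @return A list of class `toy_msa`: `msa` (a `ribo_msa`), and `truth`
#'   with `planted_columns`, `planted_letters`, and `mapped_positions`
#'   (1-based residue ordinals in a gap-free reference chain).
#' @export
make_toy_msa <- function(spec = toy_msa_spec()) {
  local_seed(spec$seed, {
    m <- matrix("", spec$n_rows, spec$n_columns)
    for (i in seq_len(spec$n_rows)) {
      m[i, ] <- sample(AA20, spec$n_columns, replace = TRUE,
                       prob = spec$background)
    }
    if (spec$gap_rate > 0) {
      gapped <- matrix(runif(length(m)) < spec$gap_rate,
                       spec$n_rows, spec$n_columns)
      gapped[1, ] <- FALSE       # reference row stays gap-free
      m[gapped] <- "-"
    }
    planted_letters <- sample(AA20, length(spec$planted_columns),
                              replace = TRUE)
    for (j in seq_along(spec$planted_columns)) {
      m[, spec$planted_columns[j]] <- planted_letters[j]
    }
    ids <- c(spec$reference_row_id,
             sprintf("seq%02d", seq_len(spec$n_rows - 1)))
    out <- msa(setNames(apply(m, 1, paste, collapse = ""), ids))
    # self-certification: planted columns invariant, gap-free
    mm <- msa_matrix(out)
    for (j in seq_along(spec$planted_columns)) {
      col <- mm[, spec$planted_columns[j]]
      stopifnot(all(col == planted_letters[j]))
    }
    structure(
      list(msa = out,
           truth = list(planted_columns = spec$planted_columns,
                        planted_letters = planted_letters,
                        mapped_positions = spec$planted_columns),
           spec = spec),
      class = "toy_msa"
    )
  })
}

#' Write a toy alignment fixture
#'
#' Emits `alignment.fasta` and `truth.json` under `dir`.
#'
#' @param toy A `toy_msa` from [make_toy_msa()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_toy_msa <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(
    as.vector(rbind(paste0(">", toy$msa$id), toy$msa$sequence)),
    file.path(dir, "alignment.fasta")
  )
  jsonlite::write_json(toy$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
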