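#' Clash-screen parameters
#'
#' A clash is a backbone-backbone atom pair strictly closer than
#' `clash_cutoff` (default 2.0 A, a deliberately permissive threshold that
#' tolerates some unknown conformational rearrangement of assembly
#' components not seen by the binary docking). The anchor chain is
#' excluded from the context by default: the docking itself already
#' accounts for ligand-anchor geometry.
#'
#' @param clash_cutoff Backbone clash cutoff, Angstrom (> 0).
#' @param excluded_chains Chain ids removed from the context before
#'   screening; `NULL` means "exclude the anchor chain" downstream.
#' @return Named list of parameters.
#' @export
clash_params <- function(clash_cutoff = 2.0, excluded_chains = NULL) {
  stopifnot(clash_cutoff > 0)
  list(clash_cutoff = clash_cutoff, atom_class = "backbone",
       excluded_chains = excluded_chains)
}

#' Superpose a docked receptor onto the anchor chain of an assembly
#'
#' Fits the docking-frame receptor onto the copy of the same chain inside
#' the full assembly, on CA atoms of residues matched by author number
#' (intersection of the two numbering sets). The returned transform maps
#' docking-frame coordinates into assembly coordinates, letting every
#' docking pose be transplanted into the assembly.
#'
#' @param docked_receptor `ribo_atoms` of the receptor as used in docking.
#' @param assembly `ribo_atoms` of the full context assembly.
#' @param anchor_chain_id Chain id of the receptor's copy in the assembly.
#' @return A `superposition` (see [kabsch_superpose()]).
#' @export
anchor_superpose <- function(docked_receptor, assembly, anchor_chain_id) {
  if (!anchor_chain_id %in% assembly$chain) {
    abort(paste0("anchor chain '", anchor_chain_id, "' not in assembly; ",
                 "available: ", paste(unique(assembly$chain), collapse = " ")))
  }
  mob <- dplyr::filter(docked_receptor, .data$atom == "CA",
                       .data$polymer == "protein")
  tgt <- dplyr::filter(assembly, .data$chain == anchor_chain_id,
                       .data$atom == "CA", .data$polymer == "protein")
  shared <- intersect(mob$resi, tgt$resi)
  if (length(shared) < 3) {
    abort(sprintf(paste0(
      "fewer than 3 residues matched by author number between the docked ",
      "receptor (%d-%d) and anchor chain %s (%d-%d)"),
      min(mob$resi), max(mob$resi), anchor_chain_id,
      min(tgt$resi), max(tgt$resi)))
  }
  mob <- dplyr::filter(mob, .data$resi %in% shared) |>
    dplyr::distinct(.data$resi, .keep_all = TRUE) |>
    dplyr::arrange(.data$resi)
  tgt <- dplyr::filter(tgt, .data$resi %in% shared) |>
    dplyr::distinct(.data$resi, .keep_all = TRUE) |>
    dplyr::arrange(.data$resi)
  kabsch_superpose(coords(mob), coords(tgt))
}

#' Place a docking pose into assembly coordinates
#'
#' Applies `anchor_transform o pose` to the ligand: the pose puts the
#' ligand into the docking receptor frame, the anchor transform carries
#' that frame into the assembly. The placement is rigid — all intra-ligand
#' distances are preserved.
#'
#' @param pose A [rigid_transform()] (one pose of a pose set).
#' @param ligand `ribo_atoms` of the ligand in its docking-input frame.
#' @param anchor_transform The transform from [anchor_superpose()] (either
#'   the `superposition` object or its `$transform`).
#' @return The ligand atom table with placed coordinates.
#' @export
place_pose <- function(pose, ligand, anchor_transform) {
  if (inherits(anchor_transform, "superposition")) {
    anchor_transform <- anchor_transform$transform
  }
  apply_transform(ligand, compose_transforms(anchor_transform, pose))
}

#' Screen a placed ligand for backbone clashes against the context
#'
#' Counts backbone-backbone atom pairs (polymer-type-aware backbone
#' definitions: protein N/CA/C/O, nucleic sugar-phosphate trace) strictly
#' closer than the clash cutoff, between the placed ligand and the context
#' assembly minus any excluded chains.
#'
#' @param placed_ligand `ribo_atoms` in assembly coordinates.
#' @param context `ribo_atoms` of the assembly.
#' @param params A [clash_params()] list.
#' @return A list of class `clash_report`: `clash_count`,
#'   `min_backbone_distance`, and `pairs` (tibble of offending ligand
#'   atom, context atom, distance).
#' @export
clash_screen <- function(placed_ligand, context, params = clash_params()) {
  if (!is.null(params$excluded_chains)) {
    context <- dplyr::filter(context,
                             !(.data$chain %in% params$excluded_chains))
  }
  if (nrow(context) == 0) abort("context is empty after excluding chains")
  lig_bb <- select_atoms(placed_ligand, "backbone")
  ctx_bb <- select_atoms(context, "backbone")
  if (nrow(lig_bb) == 0 || nrow(ctx_bb) == 0) {
    abort("no backbone atoms on one side of the clash screen")
  }
  hits <- pairs_within(lig_bb, ctx_bb, params$clash_cutoff)
  pairs <- tibble::tibble(
    ligand_chain = lig_bb$chain[hits$i], ligand_resi = lig_bb$resi[hits$i],
    ligand_atom = lig_bb$atom[hits$i],
    context_chain = ctx_bb$chain[hits$j], context_resi = ctx_bb$resi[hits$j],
    context_atom = ctx_bb$atom[hits$j],
    dist = hits$dist
  )
  structure(
    list(clash_count = nrow(pairs),
         min_backbone_distance = min_pairwise_distance(lig_bb, ctx_bb)$dist,
         cutoff = params$clash_cutoff,
         pairs = pairs),
    class = "clash_report"
  )
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(
    "<clash_report> %d clash pair(s) under %.2f A; min backbone distance %.3f A\n",
    x$clash_count, x$cutoff, x$min_backbone_distance))
  invisible(x)
}

#' Select the first clash-free pose in score order
#'
#' Iterates the ranked pose set in rank order, placing each pose into the
#' assembly and screening it for backbone clashes against the context
#' (minus the anchor chain by default); returns the first pose with zero
#' clashes. Iteration short-circuits at the selected pose unless
#' `exhaustive = TRUE`. If no pose is admissible the result carries all
#' reports and `selected_rank = NA` rather than throwing.
#'
#' @param ranked A ranked `pose_set`.
#' @param ligand `ribo_atoms` of the ligand in its docking-input frame.
#' @param anchor_transform Transform from [anchor_superpose()].
#' @param context `ribo_atoms` of the full assembly.
#' @param params A [clash_params()]; a `NULL` `excluded_chains` entry is
#'   replaced by `anchor_chain`.
#' @param anchor_chain Chain id excluded from the context by default.
#' @param exhaustive Screen every pose even after a selection is made.
#' @return A list of class `selection_result`: `selected_rank` (`NA` if
#'   none admissible), `pose` (the selected transform or `NULL`),
#'   `placed` (placed ligand atoms or `NULL`), `reports` (per-pose tibble:
#'   rank, clash_count, min_backbone_distance), and `admissible`.
#' @export
select_first_clashfree <- function(ranked, ligand, anchor_transform, context,
                                   params = clash_params(),
                                   anchor_chain = NULL,
                                   exhaustive = FALSE) {
  if (anyNA(ranked$rank)) abort("pose set is not ranked; call rank_poses()")
  if (is.null(params$excluded_chains)) {
    params$excluded_chains <- anchor_chain
  }
  ord <- order(ranked$rank)
  reports <- vector("list", nrow(ranked))
  selected <- NULL
  for (k in ord) {
    placed <- place_pose(pose_transform(ranked, k), ligand, anchor_transform)
    rep_k <- clash_screen(placed, context, params)
    reports[[k]] <- tibble::tibble(
      rank = ranked$rank[k], score = ranked$score[k],
      clash_count = rep_k$clash_count,
      min_backbone_distance = rep_k$min_backbone_distance
    )
    if (is.null(selected) && rep_k$clash_count == 0) {
      selected <- list(rank = ranked$rank[k], row = k, placed = placed,
                       report = rep_k)
      if (!exhaustive) break
    }
  }
  reports <- dplyr::bind_rows(reports[!vapply(reports, is.null, logical(1))])
  reports <- dplyr::arrange(reports, .data$rank)
  structure(
    list(
      selected_rank = if (is.null(selected)) NA_integer_ else selected$rank,
      pose = if (is.null(selected)) NULL else pose_transform(ranked,
                                                             selected$row),
      placed = if (is.null(selected)) NULL else selected$placed,
      reports = reports,
      admissible = !is.null(selected),
      params = params
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$admissible) {
    cat(sprintf("<selection_result> selected rank %d (first clash-free of %d screened)\n",
                x$selected_rank, nrow(x$reports)))
  } else {
    cat(sprintf("<selection_result> none admissible (%d poses screened, all clash)\n",
                nrow(x$reports)))
  }
  invisible(x)
}

#' Steric overlap of a placed ligand with a partner assembly
#'
#' Runs the backbone clash machinery against a partner subunit (no chains
#' excluded): a nonzero clash count means partner joining is sterically
#' blocked by the bound ligand.
#'
#' @param placed_ligand `ribo_atoms` in assembly coordinates.
#' @param partner `ribo_atoms` of the partner assembly in the same frame.
#' @param params A [clash_params()] (excluded chains forced empty).
#' @return A `clash_report` with an extra `blocked` flag.
#' @export
partner_overlap <- function(placed_ligand, partner, params = clash_params()) {
  params$excluded_chains <- NULL
  rep <- clash_screen(placed_ligand, partner, params)
  rep$blocked <- rep$clash_count > 0
  rep
}
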