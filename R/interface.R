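#' Residue-level interface contacts
#'
#' Two residues of opposing molecules are in contact when any pair of
#' their heavy atoms lies strictly closer than the cutoff (default 4.6 A).
#' Contacts are reported at residue granularity with the achieving atom
#' pair and exact minimum distance retained.
#'
#' @param ligand_atoms,receptor_atoms `ribo_atoms` tibbles (hydrogens are
#'   excluded internally).
#' @param cutoff Heavy-atom contact cutoff, Angstrom (default 4.6).
#' @return A tibble of class `contact_map`, one row per residue pair:
#'   `ligand_chain`, `ligand_resi`, `ligand_resn`, `receptor_chain`,
#'   `receptor_resi`, `receptor_resn`, `min_dist`, `ligand_atom`,
#'   `receptor_atom`, `n_atom_pairs`; sorted by `min_dist`. The cutoff is
#'   kept in the `"cutoff"` attribute.
#' @export
interface_contacts <- function(ligand_atoms, receptor_atoms, cutoff = 4.6) {
  lig <- select_atoms(ligand_atoms, "heavy")
  rec <- select_atoms(receptor_atoms, "heavy")
  if (nrow(lig) == 0 || nrow(rec) == 0) abort("empty heavy-atom set")
  hits <- pairs_within(lig, rec, cutoff)
  if (nrow(hits) == 0) {
    out <- tibble::tibble(
      ligand_chain = character(), ligand_resi = integer(),
      ligand_resn = character(), receptor_chain = character(),
      receptor_resi = integer(), receptor_resn = character(),
      min_dist = numeric(), ligand_atom = character(),
      receptor_atom = character(), n_atom_pairs = integer()
    )
    attr(out, "cutoff") <- cutoff
    class(out) <- unique(c("contact_map", class(out)))
    return(out)
  }
  out <- tibble::tibble(
    ligand_chain = lig$chain[hits$i], ligand_resi = lig$resi[hits$i],
    ligand_resn = lig$resn[hits$i], ligand_atom = lig$atom[hits$i],
    receptor_chain = rec$chain[hits$j], receptor_resi = rec$resi[hits$j],
    receptor_resn = rec$resn[hits$j], receptor_atom = rec$atom[hits$j],
    dist = hits$dist
  ) |>
    dplyr::group_by(.data$ligand_chain, .data$ligand_resi, .data$ligand_resn,
                    .data$receptor_chain, .data$receptor_resi,
                    .data$receptor_resn) |>
    dplyr::summarise(
      min_dist = min(.data$dist),
      ligand_atom = .data$ligand_atom[which.min(.data$dist)],
      receptor_atom = .data$receptor_atom[which.min(.data$dist)],
      n_atom_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$min_dist)
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("contact_map", class(out)))
  out
}

#' Interface residue sets of a contact map
#'
#' @param contact_map A `contact_map` tibble.
#' @param side `"ligand"` or `"receptor"`.
#' @return A tibble of the distinct interface residues on that side.
#' @export
interface_residues <- function(contact_map, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  cols <- paste0(side, c("_chain", "_resi", "_resn"))
  out <- dplyr::distinct(tibble::as_tibble(contact_map)[, cols])
  names(out) <- c("chain", "resi", "resn")
  dplyr::arrange(out, .data$chain, .data$resi)
}

#' Minimum heavy-atom distance between two residues
#'
#' @param res_a,res_b `ribo_atoms` tibbles, each holding the atoms of one
#'   residue (at least one heavy atom each).
#' @return Distance in Angstrom.
#' @export
residue_pair_distance <- function(res_a, res_b) {
  a <- select_atoms(res_a, "heavy")
  b <- select_atoms(res_b, "heavy")
  if (nrow(a) == 0 || nrow(b) == 0) abort("residue without heavy atoms")
  min_pairwise_distance(a, b)$dist
}

#' Read a residue-annotation table
#'
#' Tab-separated columns `chain  resi  tag  value`; tags include
#' `bridge:B5`, `bridge:B8`, `mutagenesis:abolished`,
#' `mutagenesis:weakened`, `mutagenesis:unaffected`. Lines starting with
#' `#` are comments. (chain, resi, tag) triples must be unique.
#'
#' @param path File path.
#' @return A tibble with columns `chain`, `resi`, `tag`, `value`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", quote = "",
                           col.names = c("chain", "resi", "tag", "value"),
                           colClasses = c("character", "integer",
                                          "character", "character"))
  out <- tibble::as_tibble(tab)
  if (anyDuplicated(out[, c("chain", "resi", "tag")]) > 0) {
    abort("duplicate (chain, resi, tag) rows in annotation table")
  }
  out
}

#' Overlap of the predicted interface with intersubunit bridges
#'
#' Bridge membership is an input annotation (tags `bridge:<name>`), not
#' computed: bridge assignments come from published cryo-EM analyses. For
#' each bridge, reports the interface residues that belong to it.
#'
#' @param contact_map A `contact_map`, or a residue tibble as returned by
#'   [interface_residues()] (receptor side is used for a contact map).
#' @param annotations Annotation tibble from [read_annotations()].
#' @return A tibble with one row per (bridge, overlapping residue):
#'   `bridge`, `chain`, `resi`, plus a per-bridge `n_overlap` count.
#'   Zero rows when no bridge tags are present or no interface residue
#'   belongs to a bridge.
#' @export
bridge_overlap <- function(contact_map, annotations) {
  iface <- interface_side_residues(contact_map)
  br <- dplyr::filter(annotations, startsWith(.data$tag, "bridge:")) |>
    dplyr::mutate(bridge = sub("^bridge:", "", .data$tag))
  if (nrow(br) == 0 || nrow(iface) == 0) {
    return(tibble::tibble(bridge = character(), chain = character(),
                          resi = integer(), n_overlap = integer()))
  }
  dplyr::inner_join(br, iface, by = c("chain", "resi")) |>
    dplyr::select("bridge", "chain", "resi") |>
    dplyr::mutate(n_overlap = dplyr::n(), .by = "bridge") |>
    dplyr::arrange(.data$bridge, .data$chain, .data$resi)
}

interface_side_residues <- function(x, side = "receptor") {
  if (inherits(x, "contact_map")) {
    interface_residues(x, side)[, c("chain", "resi")]
  } else {
    tibble::as_tibble(x)[, c("chain", "resi")]
  }
}

#' Consistency of predicted interface residues with mutagenesis outcomes
#'
#' Cross-tabulates {predicted interface, not predicted} against
#' {binding-affected, unaffected} over the residues that carry a
#' mutagenesis tag. "Abolished" and "weakened" outcomes are collapsed
#' into "affected". No statistical test is attached — at these counts a
#' 2x2 table speaks for itself.
#'
#' @param contact_map A `contact_map`, or a tibble/data frame of predicted
#'   residues with columns `chain` and `resi`.
#' @param annotations Annotation tibble with `mutagenesis:*` tags.
#' @return A list of class `mutagenesis_consistency`: `table` (tibble with
#'   each residue's cell), and counts `tp`, `fp`, `fn`, `tn` (predicted &
#'   affected, predicted & unaffected, missed & affected, neither).
#' @export
mutagenesis_consistency <- function(contact_map, annotations) {
  iface <- interface_side_residues(contact_map)
  mut <- dplyr::filter(annotations, startsWith(.data$tag, "mutagenesis:")) |>
    dplyr::mutate(
      outcome = sub("^mutagenesis:", "", .data$tag),
      affected = .data$outcome %in% c("abolished", "weakened")
    )
  if (nrow(mut) == 0) abort("no mutagenesis tags in annotation table")
  tab <- mut |>
    dplyr::mutate(predicted = paste(.data$chain, .data$resi) %in%
                    paste(iface$chain, iface$resi)) |>
    dplyr::mutate(cell = dplyr::case_when(
      .data$predicted & .data$affected ~ "TP",
      .data$predicted & !.data$affected ~ "FP",
      !.data$predicted & .data$affected ~ "FN",
      TRUE ~ "TN"
    )) |>
    dplyr::select("chain", "resi", "value", "outcome", "affected",
                  "predicted", "cell")
  structure(
    list(table = tab,
         tp = sum(tab$cell == "TP"), fp = sum(tab$cell == "FP"),
         fn = sum(tab$cell == "FN"), tn = sum(tab$cell == "TN")),
    class = "mutagenesis_consistency"
  )
}

#' @export
print.mutagenesis_consistency <- function(x, ...) {
  cat(sprintf(
    "<mutagenesis_consistency> TP=%d FP=%d FN=%d TN=%d over %d mutated residues\n",
    x$tp, x$fp, x$fn, x$tn, nrow(x$table)))
  invisible(x)
}
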