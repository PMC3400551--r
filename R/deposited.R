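#' Check a deposited ligand-bound assembly model
#'
#' Integration checks against an externally produced model of the full
#' assembly with the ligand bound (for example, a published supplementary
#' PDB of the complex): named residue-pair distances are measured under
#' the heavy-atom contact rule, the ligand's residue contacts with the
#' anchor chain are mapped, and the ligand is screened for backbone
#' clashes against every other chain of the assembly except the anchor.
#'
#' The ligand chain need not be known in advance — in deposited models the
#' extra chain is identified by elimination (`ligand_chain = NULL` picks
#' the chain absent from `reference_chains`).
#'
#' @param assembly `ribo_atoms` of the ligand-bound model, or a path to
#'   its PDB file.
#' @param anchor_chain Chain id of the receptor subunit (e.g. the
#'   ribosomal protein the ligand docks onto).
#' @param ligand_chain Chain id of the bound ligand, or `NULL` to identify
#'   it by elimination against `reference_chains`.
#' @param reference_chains Chain ids of the assembly without the ligand
#'   (required when `ligand_chain` is `NULL`).
#' @param pairs Optional tibble/data frame of predicted residue pairs to
#'   measure, columns `ligand_resi` and `anchor_resi`.
#' @param contact_cutoff,clash_cutoff Heavy-atom contact and backbone
#'   clash cutoffs, Angstrom.
#' @return A list of class `deposited_model_report`: `ligand_chain`,
#'   `pair_distances` (with an `in_contact` flag per pair), `contacts`
#'   (the ligand/anchor `contact_map`), and `clash` (the `clash_report`
#'   against the rest of the assembly).
#' @export
deposited_model_check <- function(assembly, anchor_chain,
                                  ligand_chain = NULL,
                                  reference_chains = NULL, pairs = NULL,
                                  contact_cutoff = 4.6, clash_cutoff = 2.0) {
  if (is.character(assembly) && length(assembly) == 1) {
    assembly <- read_pdb(assembly)
  }
  if (is.null(ligand_chain)) {
    if (is.null(reference_chains)) {
      abort("supply ligand_chain or reference_chains to identify the ligand")
    }
    extra <- setdiff(unique(assembly$chain), reference_chains)
    if (length(extra) != 1) {
      abort(paste0("could not identify the ligand chain by elimination; ",
                   "candidates: ", paste(extra, collapse = " ")))
    }
    ligand_chain <- extra
  }
  lig <- dplyr::filter(assembly, .data$chain == ligand_chain)
  anchor <- dplyr::filter(assembly, .data$chain == anchor_chain)
  if (nrow(lig) == 0 || nrow(anchor) == 0) {
    abort("ligand or anchor chain has no atoms")
  }
  pair_distances <- NULL
  if (!is.null(pairs)) {
    pair_distances <- tibble::as_tibble(pairs)
    pair_distances$dist <- vapply(seq_len(nrow(pair_distances)), function(i) {
      residue_pair_distance(
        dplyr::filter(lig, .data$resi == pair_distances$ligand_resi[i]),
        dplyr::filter(anchor, .data$resi == pair_distances$anchor_resi[i])
      )
    }, numeric(1))
    pair_distances$in_contact <- pair_distances$dist < contact_cutoff
  }
  contacts <- interface_contacts(lig, anchor, cutoff = contact_cutoff)
  clash <- clash_screen(
    lig, assembly,
    clash_params(clash_cutoff = clash_cutoff,
                 excluded_chains = c(ligand_chain, anchor_chain))
  )
  structure(
    list(ligand_chain = ligand_chain, pair_distances = pair_distances,
         contacts = contacts, clash = clash),
    class = "deposited_model_report"
  )
}

#' @export
print.deposited_model_report <- function(x, ...) {
  cat(sprintf(
    "<deposited_model_report> ligand chain %s: %d anchor contact(s), %d clash pair(s) vs rest\n",
    x$ligand_chain, nrow(x$contacts), x$clash$clash_count))
  if (!is.null(x$pair_distances)) print(x$pair_distances)
  invisible(x)
}
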