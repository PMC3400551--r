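#' Default van der Waals radii
#'
#' @return Named numeric vector of radii (Angstrom) by element.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    H = 1.20, D = 1.20, SE = 1.90)
}

#' Theoretical maximum residue SASA (Tien et al. values)
#'
#' Per-residue theoretical maxima used to normalize residue SASA into
#' relative SASA; any published table of the same shape may be supplied
#' instead.
#'
#' @return Named numeric vector, Angstrom^2 by 3-letter residue name.
#' @export
default_max_sasa <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each heavy atom, quasi-uniform points (deterministic golden-spiral
#' construction, no seed) are placed on the probe-expanded sphere; the
#' accessible area is the fraction of points not strictly inside any
#' neighbor's expanded sphere, times the sphere area. Hydrogens are
#' excluded from both the computation and the occlusion set.
#'
#' @param atoms A `ribo_atoms` tibble.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Named per-element radii; unknown elements error unless
#'   covered by this table.
#' @return A list of class `sasa_result`: `atoms` (input heavy atoms with
#'   an `area` column), `residues` (per-residue sums with relative SASA
#'   where a maximum is tabulated), `probe`, `n_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               radii = default_vdw_radii()) {
  heavy <- select_atoms(atoms, "heavy")
  if (nrow(heavy) == 0) abort("no heavy atoms")
  unknown <- setdiff(unique(heavy$element), names(radii))
  if (length(unknown) > 0) {
    abort(paste0("no radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  r <- unname(radii[heavy$element])
  area <- cpp_sasa(coords(heavy), r, probe, as.integer(n_points))
  heavy$area <- area
  res <- heavy |>
    dplyr::summarise(
      resn = dplyr::first(.data$resn),
      area = sum(.data$area),
      .by = c("chain", "resi", "icode")
    ) |>
    dplyr::mutate(
      max_area = unname(default_max_sasa()[.data$resn]),
      rel_sasa = .data$area / .data$max_area
    )
  structure(
    list(atoms = heavy, residues = tibble::as_tibble(res),
         probe = probe, n_points = n_points),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result> total %.1f A^2 over %d heavy atoms (probe %.2f A, %d points)\n",
    sum(x$atoms$area), nrow(x$atoms), x$probe, x$n_points))
  invisible(x)
}

#' Exposure parameters
#'
#' @param rel_sasa_min Minimum relative SASA (isolated receptor) for a
#'   residue to count as surface exposed (default 0.25).
#' @param partner_dist_max Maximum heavy-atom distance to the partner
#'   assembly for exposure to face the partner interface (default 10 A).
#' @param sasa_n_points Sphere points for the underlying SASA call.
#' @return Named list of parameters.
#' @export
exposure_params <- function(rel_sasa_min = 0.25, partner_dist_max = 10,
                            sasa_n_points = 960) {
  list(rel_sasa_min = rel_sasa_min, partner_dist_max = partner_dist_max,
       sasa_n_points = sasa_n_points)
}

#' Residues exposed toward the partner-subunit interface
#'
#' A residue is interface-exposed when (i) its relative SASA in the
#' isolated receptor assembly is at least `rel_sasa_min`, and (ii) its
#' minimum heavy-atom distance to the partner assembly (in a reference
#' complex providing both in one frame) is below `partner_dist_max`. With
#' no partner supplied the criterion degrades to SASA-only and the result
#' is flagged accordingly.
#'
#' @param receptor_assembly `ribo_atoms` of the receptor (isolated frame
#'   for the SASA term; same frame as `partner` for the distance term).
#' @param partner_assembly `ribo_atoms` of the partner, or `NULL`.
#' @param chain Restrict the report to one chain id (optional).
#' @param params An [exposure_params()] list.
#' @return A tibble, one row per residue: `chain`, `resi`, `resn`,
#'   `rel_sasa`, `partner_dist`, `exposed`, with attribute
#'   `"sasa_only" = TRUE` when no partner was supplied.
#' @export
interface_exposure <- function(receptor_assembly, partner_assembly = NULL,
                               chain = NULL, params = exposure_params()) {
  sr <- shrake_rupley_sasa(receptor_assembly, n_points = params$sasa_n_points)
  res <- sr$residues
  if (!is.null(chain)) {
    chain_ids <- chain
    res <- dplyr::filter(res, .data$chain %in% chain_ids)
  }
  sasa_only <- is.null(partner_assembly)
  if (sasa_only) {
    warn("no partner assembly: exposure degrades to the SASA-only criterion")
    res$partner_dist <- NA_real_
    dist_ok <- TRUE
  } else {
    partner_heavy <- select_atoms(partner_assembly, "heavy")
    res$partner_dist <- vapply(seq_len(nrow(res)), function(i) {
      ratoms <- dplyr::filter(receptor_assembly,
                              .data$chain == res$chain[i],
                              .data$resi == res$resi[i],
                              .data$icode == res$icode[i])
      min_pairwise_distance(select_atoms(ratoms, "heavy"), partner_heavy)$dist
    }, numeric(1))
    dist_ok <- res$partner_dist < params$partner_dist_max
  }
  out <- res |>
    dplyr::mutate(
      exposed = !is.na(.data$rel_sasa) &
        .data$rel_sasa >= params$rel_sasa_min & dist_ok
    ) |>
    dplyr::select("chain", "resi", "resn", "rel_sasa", "partner_dist",
                  "exposed")
  attr(out, "sasa_only") <- sasa_only
  attr(out, "params") <- params
  out
}

#' Candidate binding-epitope residues
#'
#' The candidate rule used to nominate binding-site residues on the
#' receptor before any docking evidence: a residue qualifies when its
#' alignment column is in the `high` conservation tier AND it is exposed
#' toward the partner-subunit interface. If a contact map from a selected
#' docking model is supplied, each candidate is annotated with whether the
#' model predicts it in contact with the ligand.
#'
#' @param profile A `conservation_profile`.
#' @param column_map A `column_map` tying columns to receptor residues.
#' @param exposure Exposure table from [interface_exposure()].
#' @param contact_map Optional `contact_map` of the selected model.
#' @return A tibble of candidates: `chain`, `resi`, `resn`, `column`,
#'   `score`, `category`, `rel_sasa`, `partner_dist`, and `in_contact`
#'   when a contact map was supplied.
#' @export
candidate_epitope <- function(profile, column_map, exposure,
                              contact_map = NULL) {
  scored <- dplyr::inner_join(
    tibble::as_tibble(column_map)[, c("column", "chain", "resi", "resn")],
    tibble::as_tibble(profile)[, c("column", "score", "category")],
    by = "column"
  )
  out <- dplyr::inner_join(
    scored,
    tibble::as_tibble(exposure)[, c("chain", "resi", "rel_sasa",
                                    "partner_dist", "exposed")],
    by = c("chain", "resi")
  ) |>
    dplyr::filter(.data$category == "high", .data$exposed) |>
    dplyr::select(-"exposed") |>
    dplyr::arrange(.data$chain, .data$resi)
  if (!is.null(contact_map)) {
    iface <- interface_residues(contact_map, "receptor")
    out$in_contact <- paste(out$chain, out$resi) %in%
      paste(iface$chain, iface$resi)
  }
  out
}
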