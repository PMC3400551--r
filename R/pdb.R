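#' Read a PDB-format coordinate file into an atom table
#'
#' Parses fixed-width `ATOM`/`HETATM` records (via bio3d) into a tidy atom
#' table: one row per atom, grouped by chain and residue in file order.
#' Policies applied at parse time:
#'
#' * only the first `MODEL` of a multi-model file is kept;
#' * waters (`HOH`, `WAT`, `DOD`) are dropped;
#' * alternate locations are collapsed to the highest-occupancy altloc
#'   (ties broken by lexicographically smallest altloc id);
#' * hydrogens are retained but carry `element == "H"` (or `"D"`) so that
#'   heavy-atom selections exclude them;
#' * a blank element column is inferred from the atom name.
#'
#' Residue numbers are the author-assigned (`auth`) numbers throughout.
#'
#' @param path Path to a PDB-format text file.
#' @param keep_hetero Keep non-water `HETATM` records (ions, modified
#'   residues). Default `TRUE`.
#' @return A tibble of class `ribo_atoms` with columns `chain`, `resi`,
#'   `icode`, `resn`, `polymer`, `serial`, `atom`, `altloc`, `element`,
#'   `x`, `y`, `z`, `occ`, `hetero`. The structure id (file stem) is kept
#'   in the `"id"` attribute.
#' @seealso [write_pdb()], [select_atoms()]
#' @export
read_pdb <- function(path, keep_hetero = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)

  # first-model policy: truncate at the first ENDMDL before handing to bio3d
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(
    bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE,
                    hex = TRUE)
  )

  at <- tibble::as_tibble(pdb$atom)
  at <- tibble::tibble(
    chain   = dplyr::coalesce(as.character(at$chain), " "),
    resi    = as.integer(at$resno),
    icode   = dplyr::coalesce(as.character(at$insert), ""),
    resn    = as.character(at$resid),
    serial  = as.integer(at$eleno),
    atom    = as.character(at$elety),
    altloc  = dplyr::coalesce(as.character(at$alt), ""),
    element = dplyr::coalesce(trimws(as.character(at$elesy)), ""),
    x = at$x, y = at$y, z = at$z,
    occ = dplyr::coalesce(at$o, 1),
    hetero = at$type == "HETATM"
  )

  at <- dplyr::filter(at, !(.data$resn %in% c("HOH", "WAT", "DOD")))
  if (!keep_hetero) at <- dplyr::filter(at, !.data$hetero)
  if (nrow(at) == 0) abort(paste0("no atoms left after filtering: ", path))

  blank <- at$element == ""
  if (any(blank)) {
    at$element[blank] <- infer_element(at$atom[blank], at$hetero[blank])
  }

  at <- collapse_altlocs(at)
  at$polymer <- polymer_type(at$resn)
  at <- dplyr::relocate(at, "chain", "resi", "icode", "resn", "polymer")
  new_ribo_atoms(at, id = sub("\\.[^.]*$", "", basename(path)))
}

new_ribo_atoms <- function(tbl, id = NA_character_) {
  stopifnot(all(is.finite(tbl$x)), all(is.finite(tbl$y)), all(is.finite(tbl$z)))
  attr(tbl, "id") <- id
  class(tbl) <- unique(c("ribo_atoms", class(tbl)))
  tbl
}

validate_pdb_lines <- function(lines, path) {
  rec <- which(startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM"))
  if (length(rec) == 0) {
    abort(paste0("no ATOM/HETATM records in ", path))
  }
  short <- rec[nchar(lines[rec]) < 54]
  if (length(short) > 0) {
    abort(paste0("malformed ATOM/HETATM record (line ", short[1],
                 " of ", path, "): record shorter than coordinate fields"))
  }
  for (i in rec) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54)
    )))
    if (anyNA(xyz)) {
      abort(paste0("malformed coordinates (line ", i, " of ", path, "): '",
                   trimws(substr(lines[i], 31, 54)), "'"))
    }
  }
  invisible(TRUE)
}

# PDB-convention element inference from the atom name: a leading digit
# marks a hydrogen variant (1HB2 etc.); otherwise the first alphabetic
# character is the element. Two-letter metal names (CA = calcium, FE...)
# are only honored for HETATM records — in polymer ATOM records CA is
# always the alpha carbon.
infer_element <- function(names, hetero = FALSE) {
  two_letter <- c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CA", "CU",
                  "NI", "CO", "SE", "MO", "CD", "HG")
  hetero <- rep_len(hetero, length(names))
  vapply(seq_along(names), function(i) {
    nm <- toupper(trimws(names[i]))
    if (grepl("^[0-9]", nm)) return("H")
    letters_only <- gsub("[^A-Z]", "", nm)
    if (hetero[i] && letters_only %in% two_letter &&
        nchar(nm) == nchar(letters_only)) {
      return(letters_only)
    }
    substr(letters_only, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

collapse_altlocs <- function(at) {
  if (all(at$altloc == "")) return(at)
  at |>
    dplyr::group_by(.data$chain, .data$resi, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$serial, at$serial))
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")
RNA_RES <- c("A", "U", "G", "C", "I", "N")
DNA_RES <- c("DA", "DT", "DG", "DC", "DI", "DN")

polymer_type <- function(resn) {
  dplyr::case_when(
    resn %in% AA3 ~ "protein",
    resn %in% RNA_RES ~ "rna",
    resn %in% DNA_RES ~ "dna",
    TRUE ~ "other"
  )
}

#' Write an atom table to a PDB-format file
#'
#' Emits fixed-width `ATOM`/`HETATM` records (via bio3d) with a `TER`
#' record closing each chain. Round-tripping through [read_pdb()] preserves
#' atom count, names, and coordinates to 3 decimals.
#'
#' @param atoms A `ribo_atoms` tibble (see [read_pdb()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  stopifnot(nrow(atoms) > 0)
  if (any(nchar(trimws(atoms$chain)) > 1)) {
    abort("PDB format allows single-character chain ids only")
  }
  if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000)) {
    abort("coordinates exceed the PDB fixed-width field (|v| >= 10000)")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = ifelse(atoms$hetero, "HETATM", "ATOM"),
    resno = atoms$resi, resid = atoms$resn, eleno = atoms$serial,
    elety = atoms$atom, chain = atoms$chain, insert = atoms$icode,
    alt = ifelse(atoms$altloc == "", NA, atoms$altloc),
    o = atoms$occ, b = rep(0, nrow(atoms)), elesy = atoms$element,
    end = FALSE
  )
  out <- readLines(tmp)
  rec <- startsWith(out, "ATOM") | startsWith(out, "HETATM")
  chain_of <- ifelse(rec, substr(out, 22, 22), NA)
  blocks <- split(seq_along(out)[rec], factor(chain_of[rec],
                                              levels = unique(chain_of[rec])))
  pieces <- c(unlist(lapply(blocks, function(ix) c(out[ix], "TER")),
                     use.names = FALSE), "END")
  writeLines(pieces, path)
  invisible(path)
}

#' Split an atom table by chain
#'
#' @param atoms A `ribo_atoms` tibble.
#' @return Named list of single-chain atom tables, in file order.
#' @export
chains <- function(atoms) {
  ids <- unique(atoms$chain)
  setNames(lapply(ids, function(cid) {
    new_ribo_atoms(dplyr::filter(atoms, .data$chain == cid),
                   id = attr(atoms, "id"))
  }), ids)
}

#' Residue-level summary of an atom table
#'
#' @param atoms A `ribo_atoms` tibble.
#' @return A tibble with one row per residue (`chain`, `resi`, `icode`,
#'   `resn`, `polymer`, `n_atoms`), in file order.
#' @export
residues <- function(atoms) {
  atoms |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::summarise(
      resn = dplyr::first(.data$resn),
      polymer = dplyr::first(.data$polymer),
      n_atoms = dplyr::n(),
      .ord = min(.data$.ord),
      .by = c("chain", "resi", "icode")
    ) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
}

#' @export
print.ribo_atoms <- function(x, ...) {
  if (!all(c("chain", "resi", "icode", "resn") %in% names(x))) {
    return(NextMethod())
  }
  id <- attr(x, "id")
  res <- residues(x)
  cat(sprintf("<ribo_atoms%s> %d atoms, %d residues, %d chain(s): %s\n",
              if (!is.na(id)) paste0(" ", id) else "",
              nrow(x), nrow(res), length(unique(x$chain)),
              paste(unique(x$chain), collapse = " ")))
  NextMethod()
}
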