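#' Atom selection mini-language
#'
#' Selects atoms from an atom table with a small expression language:
#' `chain <id>`, `resi <n>` or `resi <n>-<m>`, and the class keywords
#' `heavy`, `backbone`, `protein`, `nucleic` (optionally prefixed with
#' `class`). Terms combine with `and` (intersection). Selection preserves
#' file order and is idempotent.
#'
#' Atom classes:
#' * `heavy` — every atom whose element is not H or D;
#' * `backbone` — polymer-type aware: `N, CA, C, O` for protein (`OXT`
#'   excluded); the sugar-phosphate trace `P, OP1, OP2, O5', C5', C4',
#'   C3', O3'` for RNA/DNA;
#' * `protein` / `nucleic` — by residue dictionary.
#'
#' @param atoms A `ribo_atoms` tibble.
#' @param expr Selection string, e.g. `"chain K and heavy"`,
#'   `"resi 90-120 and backbone"`.
#' @return The selected rows, file order preserved, with the expression
#'   recorded in the `"expr"` attribute.
#' @examples
#' \dontrun{
#' select_atoms(asm, "chain K and class backbone")
#' }
#' @export
select_atoms <- function(atoms, expr) {
  terms <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (term in terms) {
    keep <- keep & eval_selection_term(atoms, trimws(term))
  }
  out <- atoms[keep, , drop = FALSE]
  attr(out, "expr") <- expr
  attr(out, "id") <- attr(atoms, "id")
  out
}

eval_selection_term <- function(atoms, term) {
  tok <- strsplit(term, "\\s+")[[1]]
  if (identical(tok[1], "class") && length(tok) > 1) tok <- tok[-1]
  kw <- tok[1]
  if (kw == "chain") {
    if (length(tok) < 2) abort("'chain' needs a chain id")
    if (!tok[2] %in% atoms$chain) {
      abort(paste0("unknown chain '", tok[2], "'; available: ",
                   paste(unique(atoms$chain), collapse = " ")))
    }
    return(atoms$chain == tok[2])
  }
  if (kw == "resi") {
    if (length(tok) < 2) abort("'resi' needs a number or range")
    rng <- as.integer(strsplit(tok[2], "-")[[1]])
    if (anyNA(rng)) abort(paste0("bad residue range '", tok[2], "'"))
    if (length(rng) == 1) rng <- c(rng, rng)
    return(atoms$resi >= rng[1] & atoms$resi <= rng[2])
  }
  switch(kw,
    heavy    = is_heavy(atoms),
    backbone = is_backbone(atoms),
    protein  = atoms$polymer == "protein",
    nucleic  = atoms$polymer %in% c("rna", "dna"),
    abort(paste0("unknown selection term '", term, "'"))
  )
}

is_heavy <- function(atoms) !(atoms$element %in% c("H", "D"))

PROTEIN_BACKBONE <- c("N", "CA", "C", "O")
NUCLEIC_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

is_backbone <- function(atoms) {
  (atoms$polymer == "protein" & atoms$atom %in% PROTEIN_BACKBONE) |
    (atoms$polymer %in% c("rna", "dna") & atoms$atom %in% NUCLEIC_BACKBONE)
}

#' Coordinate matrix of an atom table
#'
#' @param atoms A `ribo_atoms` tibble (or any table with `x`, `y`, `z`).
#' @return An n-by-3 numeric matrix.
#' @export
coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Replace the coordinates of an atom table
#'
#' @param atoms A `ribo_atoms` tibble.
#' @param xyz An n-by-3 matrix.
#' @return `atoms` with new coordinates.
#' @export
set_coords <- function(atoms, xyz) {
  stopifnot(nrow(xyz) == nrow(atoms), ncol(xyz) == 3)
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}
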