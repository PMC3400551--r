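#' Read a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments (via seqinr) into a tidy MSA table.
#' Lowercase letters are normalized to uppercase; `.` gaps to `-`. Rows
#' must be equal length and contain only amino-acid letters and gaps.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return A tibble of class `ribo_msa` with columns `id` and `sequence`;
#'   the alignment width is kept in the `"n_columns"` attribute.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  msa(setNames(toupper(unlist(aln$seq)), aln$nam))
}

#' Construct an MSA table from named sequences
#'
#' @param sequences Named character vector of aligned sequences.
#' @return A `ribo_msa` tibble.
#' @export
msa <- function(sequences) {
  sequences <- gsub(".", "-", toupper(sequences), fixed = TRUE)
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1) {
    off <- names(sequences)[widths != widths[1]][1]
    abort(paste0("ragged alignment: record '", off, "' has ",
                 widths[widths != widths[1]][1], " columns, expected ",
                 widths[1]))
  }
  bad <- grepl("[^A-Z\\-]", sequences)
  if (any(bad)) {
    abort(paste0("invalid characters in record '",
                 names(sequences)[bad][1], "'"))
  }
  out <- tibble::tibble(id = names(sequences), sequence = unname(sequences))
  attr(out, "n_columns") <- widths[1]
  class(out) <- unique(c("ribo_msa", class(out)))
  out
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$sequence, ""))
  rownames(m) <- msa$id
  m
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Jensen-Shannon divergence (bits) between two distributions
jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# divergence of a point mass from the uniform background: the maximum
# attainable, used to normalize scores onto [0, 1]
jsd_max <- function(k = 20) {
  jsd(c(1, rep(0, k - 1)), rep(1 / k, k))
}

#' Per-column conservation from an MSA
#'
#' For each column, the score is the Jensen-Shannon divergence between the
#' column's amino-acid frequency distribution (gaps excluded) and the
#' uniform background over the 20 amino acids, normalized by the
#' divergence of a fully conserved column so that scores lie in
#' \eqn{[0, 1]}, then multiplied by `1 - gap fraction`. An invariant
#' gap-free column scores exactly 1; a column uniform over all 20 residues
#' scores 0. All-gap columns score 0 and are flagged.
#'
#' @param msa A `ribo_msa` tibble with at least 2 rows.
#' @param tiers Tier thresholds passed to [categorize_conservation()]; the
#'   returned profile carries categories as well as scores.
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `score`, `gap_fraction`, `all_gap`, `category`.
#' @export
conservation_profile <- function(msa, tiers = c(high = 0.8, moderate = 0.5)) {
  if (nrow(msa) < 2) abort("need at least 2 aligned sequences")
  m <- msa_matrix(msa)
  norm <- jsd_max(length(AA20))
  u <- rep(1 / length(AA20), length(AA20))
  per_col <- apply(m, 2, function(col) {
    gaps <- col == "-"
    gap_frac <- mean(gaps)
    aa <- col[!gaps]
    if (length(aa) == 0) return(c(score = 0, gap_fraction = 1, all_gap = 1))
    p <- tabulate(factor(aa, levels = AA20), nbins = length(AA20))
    p <- p / sum(p)
    c(score = jsd(p, u) / norm * (1 - gap_frac),
      gap_fraction = gap_frac, all_gap = 0)
  })
  if (any(per_col["all_gap", ] == 1)) {
    warn(sprintf("%d all-gap column(s) scored 0",
                 sum(per_col["all_gap", ] == 1)))
  }
  out <- tibble::tibble(
    column = seq_len(ncol(m)),
    score = unname(per_col["score", ]),
    gap_fraction = unname(per_col["gap_fraction", ]),
    all_gap = unname(per_col["all_gap", ] == 1)
  )
  out$category <- categorize_conservation(out$score, tiers)
  attr(out, "method") <- "normalized Jensen-Shannon divergence vs uniform"
  attr(out, "tiers") <- tiers
  class(out) <- unique(c("conservation_profile", class(out)))
  out
}

#' Three-tier conservation categories
#'
#' Deterministic binning of conservation scores, mirroring the common
#' three-color rendering of conservation on structures: `high` for
#' `score >= tiers["high"]`, `moderate` for `score >= tiers["moderate"]`
#' (lower tier edges inclusive), `low` otherwise.
#'
#' @param score Numeric scores in \eqn{[0, 1]}.
#' @param tiers Named thresholds `c(high = 0.8, moderate = 0.5)`.
#' @return Character vector of categories.
#' @export
categorize_conservation <- function(score,
                                    tiers = c(high = 0.8, moderate = 0.5)) {
  stopifnot(tiers["high"] > tiers["moderate"])
  dplyr::case_when(
    score >= tiers[["high"]] ~ "high",
    score >= tiers[["moderate"]] ~ "moderate",
    TRUE ~ "low"
  )
}

#' Map alignment columns to structure residues
#'
#' The k-th non-gap position of the reference row maps to the k-th residue
#' of the chain, giving the alignment-number to residue-number
#' correspondence needed to paint conservation onto a structure. Reference
#' letters are checked against the chain's one-letter sequence; mismatches
#' are attached as a report rather than discarded.
#'
#' @param msa A `ribo_msa` tibble.
#' @param reference_row_id Row `id` of the structure's sequence in the MSA.
#' @param chain_residues Residue table of the target chain (see
#'   [residues()]), in sequence order.
#' @return A tibble of class `column_map` with columns `column`, `chain`,
#'   `resi`, `resn`, `ref_letter`, `matches`; any mismatch rows are also
#'   kept in the `"mismatches"` attribute.
#' @export
map_columns_to_residues <- function(msa, reference_row_id, chain_residues) {
  row <- msa$sequence[msa$id == reference_row_id]
  if (length(row) != 1) {
    abort(paste0("reference row '", reference_row_id, "' not found"))
  }
  letters_ref <- strsplit(row, "")[[1]]
  non_gap <- which(letters_ref != "-")
  if (length(non_gap) == 0) abort("reference row is all gaps")
  if (nrow(chain_residues) < length(non_gap)) {
    abort(sprintf(
      "chain has %d residues but the reference row has %d non-gap columns",
      nrow(chain_residues), length(non_gap)))
  }
  res <- chain_residues[seq_along(non_gap), ]
  out <- tibble::tibble(
    column = non_gap,
    chain = res$chain, resi = res$resi, resn = res$resn,
    ref_letter = letters_ref[non_gap],
    matches = letters_ref[non_gap] == one_letter(res$resn)
  )
  attr(out, "mismatches") <- dplyr::filter(out, !.data$matches)
  class(out) <- unique(c("column_map", class(out)))
  out
}

ONE_LETTER <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                MSE = "M", SEC = "U", PYL = "O")

one_letter <- function(resn) {
  out <- unname(ONE_LETTER[resn])
  out[is.na(out)] <- "X"
  out
}

#' Most conserved mapped residues
#'
#' The k residues whose alignment columns have the highest conservation
#' scores; ties are broken by ascending column index.
#'
#' @param profile A `conservation_profile`.
#' @param column_map A `column_map` from [map_columns_to_residues()].
#' @param k Number of residues (>= 1).
#' @return A tibble of the top-k residues with their columns and scores.
#' @export
top_conserved <- function(profile, column_map, k) {
  stopifnot(k >= 1)
  dplyr::inner_join(tibble::as_tibble(column_map),
                    tibble::as_tibble(profile)[, c("column", "score",
                                                   "category")],
                    by = "column") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$column) |>
    head(k)
}
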