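#' Tidiers for pipeline result objects
#'
#' `tidy()` returns the per-item table of a result (per-pose clash
#' reports, per-pair clashes, per-residue cells); `glance()` a one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name ribosite-tidiers
NULL

#' @rdname ribosite-tidiers
#' @export
tidy.selection_result <- function(x, ...) x$reports

#' @rdname ribosite-tidiers
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    selected_rank = x$selected_rank,
    admissible = x$admissible,
    n_screened = nrow(x$reports),
    clash_cutoff = x$params$clash_cutoff
  )
}

#' @rdname ribosite-tidiers
#' @export
tidy.clash_report <- function(x, ...) x$pairs

#' @rdname ribosite-tidiers
#' @export
glance.clash_report <- function(x, ...) {
  tibble::tibble(
    clash_count = x$clash_count,
    min_backbone_distance = x$min_backbone_distance,
    cutoff = x$cutoff,
    blocked = x$blocked %||% NA
  )
}

#' @rdname ribosite-tidiers
#' @export
tidy.mutagenesis_consistency <- function(x, ...) x$table

#' @rdname ribosite-tidiers
#' @export
glance.mutagenesis_consistency <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' @rdname ribosite-tidiers
#' @export
tidy.sasa_result <- function(x, ...) x$residues

#' @rdname ribosite-tidiers
#' @export
glance.sasa_result <- function(x, ...) {
  tibble::tibble(
    total_area = sum(x$atoms$area),
    n_atoms = nrow(x$atoms),
    probe = x$probe,
    n_points = x$n_points
  )
}

#' @rdname ribosite-tidiers
#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' Plot per-pose clash counts of a selection
#'
#' Clash count against pose rank with the selected (first clash-free)
#' pose highlighted.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- object$reports
  df$selected <- !is.na(object$selected_rank) &
    df$rank == object$selected_rank
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$clash_count)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$selected),
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "pose rank (docking-score order)",
                  y = "backbone clash pairs",
                  title = if (object$admissible) {
                    sprintf("first clash-free pose: rank %d",
                            object$selected_rank)
                  } else "no admissible pose") +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile
#'
#' Per-column conservation score colored by tier.
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$column, y = .data$score,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(high = "magenta3",
                                          moderate = "grey60",
                                          low = "turquoise3")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "alignment column",
                  y = "conservation (normalized JSD)") +
    ggplot2::theme_minimal()
}

#' Plot an interface contact map
#'
#' Residue-pair tile map shaded by minimum heavy-atom distance.
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$receptor_resi),
                               y = factor(.data$ligand_resi),
                               fill = .data$min_dist)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  name = "min distance (Å)") +
    ggplot2::labs(x = "receptor residue", y = "ligand residue") +
    ggplot2::theme_minimal()
}
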