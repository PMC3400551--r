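#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) plus a translation, applied as `y = R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation matrix is not orthonormal")
  }
  if (det(rotation) < 0) abort("rotation has determinant -1 (reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates or an atom table
#'
#' @param x An n-by-3 coordinate matrix or a `ribo_atoms` tibble.
#' @param transform A `rigid_transform`.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (is.matrix(x)) {
    return(t(transform$rotation %*% t(x)) +
             matrix(transform$translation, nrow(x), 3, byrow = TRUE))
  }
  set_coords(x, apply_transform(coords(x), transform))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(outer, inner)` returns the transform equivalent to
#' applying `inner` first, then `outer`.
#'
#' @param outer,inner `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(outer, inner) {
  rigid_transform(outer$rotation %*% inner$rotation,
                  as.numeric(outer$rotation %*% inner$translation) +
                    outer$translation)
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `target` over paired points. Reflections are disallowed:
#' the determinant of the returned rotation is +1.
#'
#' @param mobile,target n-by-3 coordinate matrices with matched rows,
#'   n >= 3.
#' @return A list of class `superposition` with elements `transform`
#'   (a [rigid_transform()]), `rmsd` (Angstrom), and `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) {
    abort(sprintf("point counts differ: %d vs %d", nrow(mobile), nrow(target)))
  }
  if (nrow(mobile) < 3) abort("need at least 3 paired points")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  h <- crossprod(a, b)           # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.numeric(rot %*% cm)
  fitted <- t(rot %*% t(mobile)) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  structure(
    list(transform = rigid_transform(rot, tr), rmsd = rmsd,
         n_atoms = nrow(mobile)),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Minimum pairwise distance between two atom sets
#'
#' Uses a spatial hash so the cost is sub-quadratic in practice. The
#' achieving atom pair is reported.
#'
#' @param a,b `ribo_atoms` tibbles or n-by-3 coordinate matrices.
#' @return A list with `dist` (Angstrom), and `i`, `j` — row indices of
#'   the achieving pair in `a` and `b`.
#' @export
min_pairwise_distance <- function(a, b) {
  ca <- if (is.matrix(a)) a else coords(a)
  cb <- if (is.matrix(b)) b else coords(b)
  if (nrow(ca) == 0 || nrow(cb) == 0) abort("empty atom set")
  r <- cpp_min_pairwise(ca, cb)
  list(dist = unname(r["dist"]), i = as.integer(r["i"]), j = as.integer(r["j"]))
}

#' All cross pairs closer than a cutoff
#'
#' Returns exactly the atom pairs with distance strictly below `cutoff`
#' (matching the "less than" convention used for both the 2.0 A clash rule
#' and the 4.6 A contact rule: a pair at exactly the cutoff is outside).
#'
#' @param a,b `ribo_atoms` tibbles or n-by-3 coordinate matrices.
#' @param cutoff Distance cutoff in Angstrom, > 0.
#' @return A tibble with columns `i`, `j` (row indices into `a` and `b`)
#'   and `dist`, sorted by distance ascending.
#' @export
pairs_within <- function(a, b, cutoff) {
  stopifnot(cutoff > 0)
  ca <- if (is.matrix(a)) a else coords(a)
  cb <- if (is.matrix(b)) b else coords(b)
  if (nrow(ca) == 0 || nrow(cb) == 0) abort("empty atom set")
  res <- tibble::as_tibble(cpp_pairs_within(ca, cb, cutoff))
  dplyr::arrange(res, .data$dist, .data$i, .data$j)
}
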