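#' Pose tables
#'
#' A pose set is a tibble with one rigid-body pose per row: the rotation
#' (row-major `r11`..`r33`) and translation (`tx`,`ty`,`tz`) applied to
#' the ligand in the receptor frame, a docking `score` (higher is better),
#' a 1-based `rank` assigned by [rank_poses()], and a `source` tag
#' (`"internal"` or `"imported"`).
#'
#' @param transforms List of [rigid_transform()] objects.
#' @param score Numeric scores (higher is better), or `NA` if unscored.
#' @param source `"internal"` or `"imported"`.
#' @param receptor_id,ligand_id Identifiers carried as attributes.
#' @return A `pose_set` tibble.
#' @export
pose_set <- function(transforms, score = NA_real_, source = "internal",
                     receptor_id = NA_character_, ligand_id = NA_character_) {
  rot <- t(vapply(transforms, function(p) as.numeric(t(p$rotation)),
                  numeric(9)))
  tra <- t(vapply(transforms, function(p) p$translation, numeric(3)))
  out <- tibble::tibble(
    rank = NA_integer_,
    score = rep_len(as.numeric(score), length(transforms)),
    r11 = rot[, 1], r12 = rot[, 2], r13 = rot[, 3],
    r21 = rot[, 4], r22 = rot[, 5], r23 = rot[, 6],
    r31 = rot[, 7], r32 = rot[, 8], r33 = rot[, 9],
    tx = tra[, 1], ty = tra[, 2], tz = tra[, 3],
    source = rep_len(source, length(transforms))
  )
  attr(out, "receptor_id") <- receptor_id
  attr(out, "ligand_id") <- ligand_id
  class(out) <- unique(c("pose_set", class(out)))
  out
}

#' Extract the rigid transform of one pose
#'
#' @param poses A `pose_set` tibble.
#' @param row Row index (not rank) of the pose.
#' @return A [rigid_transform()].
#' @export
pose_transform <- function(poses, row) {
  p <- poses[row, ]
  rigid_transform(
    matrix(c(p$r11, p$r12, p$r13, p$r21, p$r22, p$r23, p$r31, p$r32, p$r33),
           3, 3, byrow = TRUE),
    c(p$tx, p$ty, p$tz)
  )
}

#' Desk-scale rigid-body pose sampler
#'
#' A deliberately simple docking surrogate for generating contacting,
#' clash-diverse pose ensembles: ligand orientations are drawn uniformly
#' over SO(3) (quaternion method), approach directions uniformly over the
#' sphere, and for each (orientation, direction) the ligand is slid along
#' the center-to-center axis until its closest heavy-atom distance to the
#' receptor equals `touch_distance` (first touch, bisection to 0.01 A).
#' Every returned pose therefore has at least one receptor-ligand
#' heavy-atom pair inside the contact cutoff. Poses are scored with
#' [score_pose()] and ranked.
#'
#' @param receptor,ligand `ribo_atoms` tibbles.
#' @param n_rotations,n_translations Sample counts (>= 1).
#' @param seed Integer seed; the sampler is deterministic given the seed.
#' @param touch_distance Closest-approach distance at first touch
#'   (Angstrom, default 4.0, inside the 4.6 A contact cutoff).
#' @param params Scoring parameters, see [score_pose()].
#' @return A ranked `pose_set` of `n_rotations * n_translations` poses.
#' @export
enumerate_poses <- function(receptor, ligand, n_rotations, n_translations,
                            seed, touch_distance = 4.0,
                            params = score_params()) {
  stopifnot(nrow(receptor) > 0, nrow(ligand) > 0,
            n_rotations >= 1, n_translations >= 1)
  rec_h <- coords(select_atoms(receptor, "heavy"))
  lig_h <- coords(select_atoms(ligand, "heavy"))
  rc <- colMeans(rec_h)
  lc <- colMeans(lig_h)
  r_rec <- max(sqrt(rowSums(sweep(rec_h, 2, rc)^2)))
  r_lig <- max(sqrt(rowSums(sweep(lig_h, 2, lc)^2)))
  shell <- r_rec + r_lig + touch_distance + 10

  transforms <- local_seed(seed, {
    out <- vector("list", n_rotations * n_translations)
    k <- 0
    for (ir in seq_len(n_rotations)) {
      rot <- random_rotation()
      lig_rot <- sweep(lig_h, 2, lc) %*% t(rot)   # centered, rotated ligand
      for (it in seq_len(n_translations)) {
        u <- random_unit_vector()
        t_touch <- slide_to_touch(rec_h, lig_rot, rc, u, shell, touch_distance)
        if (is.na(t_touch)) {
          abort("no contacting pose achievable within the search shell")
        }
        pos <- rc + u * t_touch
        k <- k + 1
        out[[k]] <- rigid_transform(rot, pos - as.numeric(rot %*% lc))
      }
    }
    out
  })

  ps <- pose_set(transforms, source = "internal",
                 receptor_id = attr(receptor, "id"),
                 ligand_id = attr(ligand, "id"))
  ps$score <- vapply(seq_len(nrow(ps)), function(i) {
    score_pose(receptor, ligand, pose_transform(ps, i), params)
  }, numeric(1))
  attr(ps, "params") <- params
  rank_poses(ps)
}

# Marsaglia/Shoemake uniform random rotation from a unit quaternion
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# distance from receptor at centroid offset t along u, bisected to the
# first-touch offset (largest t where min heavy-atom distance crosses
# `touch` coming in from outside); a coarse inward walk brackets the
# first crossing so hollow receptors are handled too
slide_to_touch <- function(rec, lig_centered, rc, u, t_max, touch,
                           tol = 0.01) {
  gap <- function(t) {
    pos <- matrix(rc + u * t, nrow(lig_centered), 3, byrow = TRUE)
    unname(cpp_min_pairwise(rec, lig_centered + pos)["dist"])
  }
  hi <- t_max
  if (gap(hi) <= touch) return(NA_real_)     # shell too small for this ligand
  step <- 1
  lo <- NA_real_
  t <- hi - step
  while (t >= 0) {
    if (gap(t) < touch) { lo <- t; break }
    hi <- t
    t <- t - step
  }
  if (is.na(lo) && gap(0) < touch) lo <- 0
  if (is.na(lo)) return(NA_real_)            # never reaches touch distance
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) < touch) lo <- mid else hi <- mid
  }
  hi
}

#' Contact-minus-clash surrogate docking score
#'
#' `score = n_contact - clash_weight * n_clash`, where `n_contact` counts
#' receptor-ligand heavy-atom pairs with `clash_cutoff <= d < contact_cutoff`
#' and `n_clash` counts pairs with `d < clash_cutoff`. Deterministic; higher
#' is better.
#'
#' @param receptor,ligand `ribo_atoms` tibbles (ligand in its own frame).
#' @param pose A [rigid_transform()] applied to the ligand.
#' @param params A [score_params()] list.
#' @return A single numeric score.
#' @export
score_pose <- function(receptor, ligand, pose, params = score_params()) {
  rec_h <- select_atoms(receptor, "heavy")
  lig_h <- apply_transform(coords(select_atoms(ligand, "heavy")), pose)
  pr <- pairs_within(coords(rec_h), lig_h, params$contact_cutoff)
  n_clash <- sum(pr$dist < params$clash_cutoff)
  n_contact <- nrow(pr) - n_clash
  n_contact - params$clash_weight * n_clash
}

#' Scoring parameters for the pose sampler
#'
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom, default 4.6).
#' @param clash_cutoff Heavy-atom clash cutoff (Angstrom, default 2.0).
#' @param clash_weight Penalty per clash pair (default 10, so a single
#'   clash outweighs a typical toy-scale contact count).
#' @return Named list of parameters.
#' @export
score_params <- function(contact_cutoff = 4.6, clash_cutoff = 2.0,
                         clash_weight = 10) {
  stopifnot(contact_cutoff > clash_cutoff, clash_cutoff > 0)
  list(contact_cutoff = contact_cutoff, clash_cutoff = clash_cutoff,
       clash_weight = clash_weight)
}

#' Rank poses by score
#'
#' Stable sort by score descending — ties keep their generation (or import)
#' order — and ranks reassigned 1..N.
#'
#' @param poses A `pose_set` tibble; all poses must be scored.
#' @return The re-ordered `pose_set` with `rank` = 1..N and non-increasing
#'   scores.
#' @export
rank_poses <- function(poses) {
  if (anyNA(poses$score)) abort("unscored pose(s): score is NA")
  ord <- order(-poses$score, seq_len(nrow(poses)))
  out <- poses[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "receptor_id") <- attr(poses, "receptor_id")
  attr(out, "ligand_id") <- attr(poses, "ligand_id")
  attr(out, "params") <- attr(poses, "params")
  out
}

#' Read / write pose tables
#'
#' Tab-separated, one pose per line —
#' `rank score r11 r12 r13 r21 r22 r23 r31 r32 r33 tx ty tz` — with `#`
#' header lines. Round-trips preserve transforms to 6 decimals, scores,
#' and order. On read, each rotation is validated (orthonormal within
#' 1e-4, determinant +1); imported files are assumed ordered best-first,
#' set `reverse = TRUE` if the external engine wrote worst-first.
#'
#' @param path File path.
#' @param reverse Reverse the row order on read.
#' @return `read_poses` returns a `pose_set` (source `"imported"`).
#' @export
read_poses <- function(path, reverse = FALSE) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("rank", "score",
                                         "r11", "r12", "r13", "r21", "r22",
                                         "r23", "r31", "r32", "r33",
                                         "tx", "ty", "tz"))
  if (reverse) tab <- tab[rev(seq_len(nrow(tab))), ]
  transforms <- lapply(seq_len(nrow(tab)), function(i) {
    r <- matrix(as.numeric(tab[i, 3:11]), 3, 3, byrow = TRUE)
    if (max(abs(crossprod(r) - diag(3))) > 1e-4) {
      abort(sprintf("pose %d: rotation is not orthonormal", i))
    }
    if (det(r) < 0) {
      abort(sprintf("pose %d: rotation has determinant -1 (reflection)", i))
    }
    rigid_transform(r, as.numeric(tab[i, 12:14]))
  })
  out <- pose_set(transforms, score = tab$score, source = "imported")
  out$rank <- as.integer(tab$rank)
  out
}

#' @rdname read_poses
#' @param poses A `pose_set` tibble.
#' @export
write_poses <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# pose table; receptor:",
                   attr(poses, "receptor_id") %||% "NA",
                   "ligand:", attr(poses, "ligand_id") %||% "NA"), con)
  writeLines("# rank score r11 r12 r13 r21 r22 r23 r31 r32 r33 tx ty tz", con)
  cols <- c("rank", "score", "r11", "r12", "r13", "r21", "r22", "r23",
            "r31", "r32", "r33", "tx", "ty", "tz")
  utils::write.table(format(as.data.frame(poses[, cols]), digits = 17,
                            scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# evaluate expr under a fixed RNG state, restoring the caller's state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
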