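# Monte-Carlo pose search with local refinement inside a user box.
#
# A pose is (translation, orientation quaternion, torsion angles). The
# translation is the absolute position of the ligand's heavy-atom centroid;
# torsions are applied root-outward along the branch tree, then the global
# rotation about the centroid, then the translation.

MAX_POSES <- 999L
DIVERSITY_RMSD <- 2.0

#' Define a rectangular search box
#'
#' @param center 3-vector, box center (Angstrom).
#' @param size 3-vector, box edge lengths (Angstrom), all positive.
#' @return A `search_box` object.
#' @export
search_box <- function(center, size) {
  stopifnot(length(center) == 3, length(size) == 3)
  if (any(size <= 0)) stop("box sizes must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), size = as.numeric(size)),
            class = "search_box")
}

in_box <- function(xyz, box, margin = 0) {
  lo <- box$center - box$size / 2 - margin
  hi <- box$center + box$size / 2 + margin
  all(xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
        xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
        xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3])
}

# -- quaternions --------------------------------------------------------------

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_random <- function() quat_normalize(rnorm(4))

quat_from_rotvec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * v / theta)
}

rotate_about_axis <- function(xyz, p1, p2, angle) {
  ax <- p2 - p1
  ax <- ax / sqrt(sum(ax^2))
  r <- quat_to_rotmat(quat_from_rotvec(ax * angle))
  sweep(sweep(xyz, 2, p1) %*% t(r), 2, p1, `+`)
}

# -- pose realization ---------------------------------------------------------

# branch order with parents before children (parse order guarantees this,
# but constructed ligands are re-checked)
branch_order <- function(ligand) {
  if (!length(ligand$branches)) return(integer(0))
  parents <- vapply(ligand$branches, `[[`, 0L, "parent_branch")
  ord <- order(seq_along(parents))
  if (any(parents >= seq_along(parents))) {
    stop("branch list must order parents before children", call. = FALSE)
  }
  ord
}

# torsion step only: rotate each branch subtree about its bond axis,
# parents before children; atoms outside a rotated subtree are untouched
apply_torsions <- function(ligand, torsions) {
  xyz <- coords_matrix(ligand$atoms)
  bo <- branch_order(ligand)
  if (length(torsions) != length(bo)) {
    stop("torsion count must equal the branch count", call. = FALSE)
  }
  for (i in bo) {
    ang <- torsions[i]
    if (abs(ang) < 1e-15) next
    b <- ligand$branches[[i]]
    moved <- branch_subtree_atoms(ligand, i)
    xyz[moved, ] <- rotate_about_axis(xyz[moved, , drop = FALSE],
                                      xyz[b$parent_atom, ],
                                      xyz[b$child_atom, ], ang)
  }
  xyz
}

realize_coords <- function(ligand, translation, orientation, torsions) {
  xyz <- apply_torsions(ligand, torsions)
  heavy <- is_heavy(ligand$atoms)
  cen <- colMeans(xyz[heavy, , drop = FALSE])
  r <- quat_to_rotmat(quat_normalize(orientation))
  xyz <- sweep(sweep(xyz, 2, cen) %*% t(r), 2, as.numeric(translation), `+`)
  xyz
}

new_pose <- function(ligand, translation, orientation, torsions, ctx) {
  xyz <- realize_coords(ligand, translation, orientation, torsions)
  heavy <- is_heavy(ligand$atoms)
  raw <- score_total(ctx, xyz[heavy, , drop = FALSE])
  structure(list(translation = as.numeric(translation),
                 orientation = quat_normalize(orientation),
                 torsions = as.numeric(torsions),
                 score = raw / (1 + W_ROT * ligand$n_rotatable),
                 coords = xyz,
                 heavy = heavy),
            class = "allodeck_pose")
}

#' @export
print.allodeck_pose <- function(x, ...) {
  cat(sprintf("<allodeck_pose> score %.3f kcal/mol, %d torsions\n",
              x$score, length(x$torsions)))
  invisible(x)
}

# ligand copy with pose coordinates baked in
apply_pose <- function(ligand, pose) {
  ligand$atoms$x <- pose$coords[, 1]
  ligand$atoms$y <- pose$coords[, 2]
  ligand$atoms$z <- pose$coords[, 3]
  ligand
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' No re-fitting is applied: poses share the receptor frame.
#'
#' @param a,b `allodeck_pose` objects for the same ligand.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  xa <- a$coords[a$heavy, , drop = FALSE]
  xb <- b$coords[b$heavy, , drop = FALSE]
  if (nrow(xa) != nrow(xb)) stop("atom-count mismatch between poses",
                                 call. = FALSE)
  sqrt(mean(rowSums((xa - xb)^2)))
}

# objective with soft box containment (used only inside dock())
penalized_score <- function(ctx, ligand, box, p, n_tor) {
  xyz <- realize_coords(ligand, p[1:3], quat_from_params(p[4:7]),
                        if (n_tor) p[7 + seq_len(n_tor)] else numeric(0))
  heavy <- is_heavy(ligand$atoms)
  hx <- xyz[heavy, , drop = FALSE]
  s <- score_total(ctx, hx)
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  over <- pmax(sweep(hx, 2, hi, `-`), 0) + pmax(sweep(-hx, 2, -lo, `-`), 0)
  s + 50 * sum(over^2)
}

quat_from_params <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-9) c(1, 0, 0, 0) else q / n
}

refine_params <- function(ctx, ligand, box, pose, maxit = 250) {
  n_tor <- length(pose$torsions)
  p0 <- c(pose$translation, pose$orientation, pose$torsions)
  fn <- function(p) penalized_score(ctx, ligand, box, p, n_tor)
  opt <- optim(p0, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
  new_pose(ligand, opt$par[1:3], quat_from_params(opt$par[4:7]),
           if (n_tor) opt$par[7 + seq_len(n_tor)] else numeric(0), ctx)
}

#' Locally refine a pose
#'
#' Gradient-free descent (Nelder-Mead over translation, orientation and
#' torsions) from the given pose; the returned pose never scores worse than
#' the input.
#'
#' @param receptor Typed `allodeck_structure`.
#' @param ligand Typed `allodeck_ligand`.
#' @param pose An `allodeck_pose`.
#' @param maxit Iteration budget for the simplex.
#' @return The refined `allodeck_pose` (the input pose if no improvement was
#'   found).
#' @export
local_refine <- function(receptor, ligand, pose, maxit = 200) {
  ctx <- score_context(receptor, ligand$atoms)
  n_tor <- length(pose$torsions)
  p0 <- c(pose$translation, pose$orientation, pose$torsions)
  fn <- function(p) {
    xyz <- realize_coords(ligand, p[1:3], quat_from_params(p[4:7]),
                          if (n_tor) p[7 + seq_len(n_tor)] else numeric(0))
    score_total(ctx, xyz[is_heavy(ligand$atoms), , drop = FALSE])
  }
  opt <- optim(p0, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  cand <- new_pose(ligand, opt$par[1:3], quat_from_params(opt$par[4:7]),
                   if (n_tor) opt$par[7 + seq_len(n_tor)] else numeric(0), ctx)
  if (cand$score <= pose$score) cand else pose
}

#' Dock a ligand into a search box
#'
#' Iterated Monte-Carlo search: random restarts, Metropolis-accepted random
#' perturbations of translation/orientation/torsions, and local simplex
#' refinement of accepted states. Returned poses are sorted by score
#' (ascending, most favorable first), mutually distinct (pairwise heavy-atom
#' RMSD at or above the 2 A diversity threshold), fully contained in the
#' box, and deterministic for a fixed seed.
#'
#' @param receptor Typed `allodeck_structure`.
#' @param ligand Typed `allodeck_ligand`.
#' @param box A [search_box()].
#' @param n_poses Number of poses requested (at most 999).
#' @param seed Integer seed for the search's random number stream.
#' @param n_runs Number of Monte-Carlo restarts (default scales with the
#'   rotatable-bond count).
#' @param n_steps Metropolis steps per restart.
#' @return An `allodeck_poses` list of `allodeck_pose`, with the search
#'   metadata (`seed`, `box`) as attributes.
#' @export
dock <- function(receptor, ligand, box, n_poses = 9L, seed = 1L,
                 n_runs = 16L + 4L * ligand$n_rotatable, n_steps = 350L) {
  if (n_poses > MAX_POSES) {
    stop("a maximum of 999 binding poses can be generated", call. = FALSE)
  }
  if (n_poses < 1) stop("n_poses must be >= 1", call. = FALSE)
  heavy_xyz <- coords_matrix(ligand$atoms[is_heavy(ligand$atoms), ])
  extent <- max(stats::dist(heavy_xyz))
  if (extent > max(box$size) * sqrt(3)) {
    stop("box too small for ligand", call. = FALSE)
  }
  # restrict the receptor to atoms that can ever interact with the box
  keep <- rep(TRUE, nrow(receptor$atoms))
  rxyz <- coords_matrix(receptor$atoms)
  lo <- box$center - box$size / 2 - SCORE_CUTOFF - 1
  hi <- box$center + box$size / 2 + SCORE_CUTOFF + 1
  keep <- rxyz[, 1] >= lo[1] & rxyz[, 1] <= hi[1] &
    rxyz[, 2] >= lo[2] & rxyz[, 2] <= hi[2] &
    rxyz[, 3] >= lo[3] & rxyz[, 3] <= hi[3]
  rec_sub <- receptor
  rec_sub$atoms <- receptor$atoms[keep, ]
  ctx <- score_context(rec_sub, ligand$atoms)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n_tor <- length(ligand$branches)
  # annealed Metropolis temperature: hot early for barrier crossing,
  # cold late so runs settle into their basin before refinement
  kT_sched <- 2.5 * (0.5 / 2.5)^(seq_len(n_steps) / n_steps)
  inner <- pmax(box$size / 2 - 1, 0.5)
  candidates <- list()
  for (run in seq_len(n_runs)) {
    t0 <- box$center + runif(3, -1, 1) * inner
    cur <- new_pose(ligand, t0, quat_random(),
                    if (n_tor) runif(n_tor, -pi, pi) else numeric(0), ctx)
    best <- cur
    for (step in seq_len(n_steps)) {
      t1 <- cur$translation + rnorm(3, 0, 0.6)
      q1 <- quat_multiply(quat_from_rotvec(rnorm(3, 0, 0.25)),
                          cur$orientation)
      tor1 <- cur$torsions
      if (n_tor) {
        j <- sample.int(n_tor, 1)
        tor1[j] <- tor1[j] + rnorm(1, 0, 0.5)
      }
      cand <- new_pose(ligand, t1, q1, tor1, ctx)
      if (!in_box(cand$coords[cand$heavy, , drop = FALSE], box)) next
      if (cand$score <= cur$score ||
            runif(1) < exp((cur$score - cand$score) / kT_sched[step])) {
        cur <- cand
        if (cur$score < best$score) best <- cur
      }
    }
    ref <- refine_params(ctx, ligand, box, best)
    if (in_box(ref$coords[ref$heavy, , drop = FALSE], box) &&
          ref$score <= best$score) best <- ref
    if (in_box(best$coords[best$heavy, , drop = FALSE], box)) {
      candidates[[length(candidates) + 1L]] <- best
    }
  }
  if (!length(candidates)) stop("search produced no pose inside the box",
                                call. = FALSE)
  scores <- vapply(candidates, `[[`, 0, "score")
  candidates <- candidates[order(scores)]
  selected <- list()
  for (cand in candidates) {
    if (length(selected) >= n_poses) break
    ok <- all(vapply(selected, function(s) pose_rmsd(s, cand), 0) >=
                DIVERSITY_RMSD) || !length(selected)
    if (ok) selected[[length(selected) + 1L]] <- cand
  }
  # decompositions are computed against the full receptor
  for (i in seq_along(selected)) {
    selected[[i]]$decomposition <-
      score_complex(receptor, apply_pose(ligand, selected[[i]]))
  }
  structure(selected, class = "allodeck_poses", seed = seed, box = box)
}

#' @export
print.allodeck_poses <- function(x, ...) {
  cat(sprintf("<allodeck_poses> %d poses, scores %s kcal/mol (seed %d)\n",
              length(x),
              paste(sprintf("%.2f", vapply(x, `[[`, 0, "score")),
                    collapse = ", "),
              attr(x, "seed")))
  invisible(x)
}

#' Write docked poses as multi-model PDBQT
#'
#' @param poses An `allodeck_poses` list.
#' @param ligand The ligand that was docked.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_pdbqt <- function(poses, ligand, path) {
  lines <- character(0)
  for (i in seq_along(poses)) {
    lines <- c(lines, sprintf("MODEL %8d", i),
               sprintf("REMARK SCORE %10.4f", poses[[i]]$score))
    lig_i <- apply_pose(ligand, poses[[i]])
    tmp <- tempfile()
    write_pdbqt(lig_i, tmp)
    lines <- c(lines, readLines(tmp), "ENDMDL")
    unlink(tmp)
  }
  writeLines(lines, path)
  invisible(path)
}
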