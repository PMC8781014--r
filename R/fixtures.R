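# Deterministic synthetic fixtures: planted-cavity receptors, toy ligands,
# and the packaged free-energy component tables. The generators are
# first-class, tested code; every stage of the package is exercisable
# offline through them.

FIXTURE_KINDS <- c("sphere_pocket", "two_pockets", "solid_ball",
                   "hinge_dimer", "toy_ligand_rigid", "toy_ligand_flex")

#' Describe a synthetic fixture
#'
#' @param kind One of `"sphere_pocket"`, `"two_pockets"`, `"solid_ball"`,
#'   `"hinge_dimer"`, `"toy_ligand_rigid"`, `"toy_ligand_flex"`.
#' @param seed Integer seed; the same `(kind, seed, params)` always yields
#'   byte-identical output.
#' @param ... Geometry overrides (see the generator defaults).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind, seed = 1L, ...) {
  if (!kind %in% FIXTURE_KINDS) {
    stop("unknown fixture kind '", kind, "'", call. = FALSE)
  }
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "fixture_spec")
}

with_fixture_rng <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# The pocket receptor is a solid lattice blob with an asymmetric,
# ligand-shaped void carved out of it (union of spheres around the planted
# ligand atoms). The void fits the rigid toy ligand in exactly one
# orientation -- its arms have distinct lengths and angles -- so the
# planted pose is the unique energy optimum: wrong orientations clash with
# the walls instead of competing through diffuse contact texture.
make_pocket_blob <- function(center, first_serial = 1L,
                             seed_offset_resseq = 0L, radius = 9.5,
                             spacing = 1.8, carve = 4.0,
                             channel_radius = 1.6, jitter_sd = 0.12,
                             with_anchors = TRUE) {
  g <- expand.grid(x = seq(-radius, radius, by = spacing),
                   y = seq(-radius, radius, by = spacing),
                   z = seq(-radius, radius, by = spacing))
  g <- as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius^2, ])
  dimnames(g) <- NULL
  g <- g + matrix(rnorm(length(g), 0, jitter_sd), nrow(g), 3)
  lig <- rigid_ligand_coords()
  lig <- lig[rownames(lig) != "H2", ]
  # carve the ligand-shaped void
  keep <- rep(TRUE, nrow(g))
  for (i in seq_len(nrow(lig))) {
    d2 <- (g[, 1] - lig[i, 1])^2 + (g[, 2] - lig[i, 2])^2 +
      (g[, 3] - lig[i, 3])^2
    keep <- keep & d2 > carve^2
  }
  # access channel along +z: a narrow perforation to the surface, too
  # tight for a heavy atom and sealed at the 1.4 A probe level (buried
  # pockets look like this in real data)
  keep <- keep & !(g[, 3] > 0 & sqrt(g[, 1]^2 + g[, 2]^2) < channel_radius)
  g <- g[keep, , drop = FALSE]
  n <- nrow(g)
  rr <- sqrt(rowSums(g^2))
  # polar serines only on the outer surface, out of reach of the void
  polar <- rr > radius - 1.5 & seq_len(n) %% 9 == 0
  at <- tibble::tibble(
    serial = first_serial + seq_len(n) - 1L,
    name = ifelse(polar, "OG", "CB"),
    resname = ifelse(polar, "SER", ifelse(seq_len(n) %% 2 == 0, "ALA", "LEU")),
    chain = "A",
    resseq = seed_offset_resseq + seq_len(n),
    x = g[, 1], y = g[, 2], z = g[, 3],
    element = ifelse(polar, "O", "C"))
  if (with_anchors) {
    # a serine-oxygen acceptor on the ligand's (protonated, donor-only)
    # N ray and a zinc site (donor-only toward acceptors) on its
    # acceptor-O ray, each at the net optimum of the hydrogen-bond ramp
    # minus the repulsion wall; with single-role partners on both sides,
    # each anchor is satisfiable by exactly one ligand arm
    ns <- max(at$serial)
    nr <- max(at$resseq)
    o_dir <- c(1, 0, 0)
    n_dir <- c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
    anchors <- tibble::tibble(
      serial = ns + 1:2,
      name = c("OG", "ZN"),
      resname = c("SER", "ZN"),
      chain = "A",
      resseq = c(nr + 1L, nr + 2L),
      x = c(4.65 * o_dir[1], 4.05 * n_dir[1]),
      y = c(4.65 * o_dir[2], 4.05 * n_dir[2]),
      z = 0,
      element = c("O", "Zn"))
    at <- rbind(at, anchors)
  }
  at$x <- at$x + center[1]; at$y <- at$y + center[2]; at$z <- at$z + center[3]
  at
}

make_blob <- function(center, n, radius, first_serial, first_resseq,
                      jitter_sd = 0.1) {
  # filled lattice ball
  g <- expand.grid(x = seq(-radius, radius, by = 1.8),
                   y = seq(-radius, radius, by = 1.8),
                   z = seq(-radius, radius, by = 1.8))
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, ]
  g <- g + matrix(rnorm(3 * nrow(g), 0, jitter_sd), nrow(g), 3)
  tibble::tibble(
    serial = first_serial + seq_len(nrow(g)) - 1L,
    name = "CB",
    resname = ifelse(seq_len(nrow(g)) %% 2 == 0, "ALA", "LEU"),
    chain = "A",
    resseq = first_resseq + seq_len(nrow(g)) - 1L,
    x = g$x + center[1], y = g$y + center[2], z = g$z + center[3],
    element = "C")
}

#' Generate a synthetic receptor with recorded ground truth
#'
#' * `sphere_pocket` - a solid blob of pseudo-residues with one interior
#'   ligand-shaped void, an access channel along +z, and two hydrogen-bond
#'   anchor atoms flanking the planted ligand pose (recorded in the truth
#'   record).
#' * `two_pockets` - two such blobs 32 A apart (two planted cavities).
#' * `solid_ball` - a filled lattice ball with no interior void.
#' * `hinge_dimer` - two compact lobes joined by a thin neck, for
#'   elastic-network tests.
#'
#' @param spec A [fixture_spec()] (or a kind string).
#' @param seed Seed when `spec` is given as a string.
#' @return `list(structure =, truth =)`; the truth record carries planted
#'   cavity centers and, for `sphere_pocket`, the planted ligand pose.
#' @export
make_receptor <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- fixture_spec(spec, seed)
  p <- spec$params
  with_fixture_rng(spec$seed, {
    if (spec$kind == "sphere_pocket") {
      at <- make_pocket_blob(c(0, 0, 0),
                             channel_radius = p$channel_radius %||% 1.6)
      # the planted pose is the deepest locally refined optimum over a
      # deterministic multistart around the carved-void center, so
      # redocking recovery measures the search, not a generator/landscape
      # mismatch
      st0 <- assign_dock_types(structure_from_atoms(at))
      lig0 <- make_ligand("toy_ligand_rigid")
      ctx0 <- score_context(st0, lig0$atoms)
      cen0 <- colMeans(coords_matrix(lig0$atoms[is_heavy(lig0$atoms), ]))
      pose1 <- NULL
      for (dx in c(-0.8, 0, 0.8)) for (dy in c(-0.8, 0, 0.8))
        for (dz in c(-0.8, 0, 0.8)) {
          p0 <- new_pose(lig0, cen0 + c(dx, dy, dz), c(1, 0, 0, 0),
                         numeric(0), ctx0)
          p1 <- local_refine(st0, lig0, p0, maxit = 250)
          if (is.null(pose1) || p1$score < pose1$score) pose1 <- p1
        }
      pose1 <- local_refine(st0, lig0, pose1, maxit = 500)
      planted <- pose1$coords
      rownames(planted) <- lig0$atoms$name
      void_cen <- colMeans(rigid_ligand_coords()[
        rownames(rigid_ligand_coords()) != "H2", ])
      truth <- list(kind = spec$kind, seed = spec$seed,
                    cavity_centers = list(void_cen),
                    planted_pose = planted,
                    planted_score = pose1$score)
    } else if (spec$kind == "two_pockets") {
      # blobs far enough apart that the space between them is open in
      # most scan directions and never reads as a third cavity
      a1 <- make_pocket_blob(c(-16, 0, 0))
      a2 <- make_pocket_blob(c(16, 0, 0),
                             first_serial = max(a1$serial) + 1L,
                             seed_offset_resseq = max(a1$resseq))
      at <- rbind(a1, a2)
      void_cen <- colMeans(rigid_ligand_coords()[
        rownames(rigid_ligand_coords()) != "H2", ])
      truth <- list(kind = spec$kind, seed = spec$seed,
                    cavity_centers = list(c(-16, 0, 0) + void_cen,
                                          c(16, 0, 0) + void_cen))
    } else if (spec$kind == "solid_ball") {
      at <- make_blob(c(0, 0, 0), radius = p$radius %||% 6,
                      n = NA, first_serial = 1L, first_resseq = 1L)
      truth <- list(kind = spec$kind, seed = spec$seed,
                    cavity_centers = list())
    } else if (spec$kind == "hinge_dimer") {
      # lobes far enough apart that no spring crosses directly; coupling
      # only through the thin neck (classic anticorrelated dumbbell)
      a1 <- make_blob(c(-14, 0, 0), NA, radius = 4, first_serial = 1L,
                      first_resseq = 1L)
      a2 <- make_blob(c(14, 0, 0), NA, radius = 4,
                      first_serial = max(a1$serial) + 1L,
                      first_resseq = max(a1$resseq) + 1L)
      # neck atoms are jittered off the hinge axis: a perfectly collinear
      # linker would leave lobe counter-rotation as a zero-energy mechanism
      neck_x <- seq(-10.5, 10.5, by = 3)
      neck <- tibble::tibble(
        serial = max(a2$serial) + seq_along(neck_x),
        name = "CB", resname = "ALA", chain = "A",
        resseq = max(a2$resseq) + seq_along(neck_x),
        x = neck_x, y = rnorm(length(neck_x), 0, 0.5),
        z = rnorm(length(neck_x), 0, 0.5), element = "C")
      at <- rbind(a1, a2, neck)
      truth <- list(kind = spec$kind, seed = spec$seed,
                    cavity_centers = list(),
                    lobes = list(left = c(-14, 0, 0), right = c(14, 0, 0)))
    } else {
      stop("unknown receptor fixture kind '", spec$kind, "'", call. = FALSE)
    }
    st <- structure_from_atoms(at, source = sprintf("fixture:%s(seed=%d)",
                                                    spec$kind, spec$seed))
    list(structure = st, truth = truth)
  })
}

rigid_ligand_coords <- function() {
  # central carbon with four arms of distinct lengths and angles (donor N,
  # acceptor O, a two-carbon arm in the plane, one out-of-plane carbon):
  # no nontrivial rotation maps the arm set onto itself, so the carved
  # pocket fits the ligand in exactly one orientation
  d100 <- c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
  d215 <- c(cos(215 * pi / 180), sin(215 * pi / 180), 0)
  rbind(C1 = c(0, 0, 0),
        N2 = c(1.5, 0, 0), H2 = c(2.5, 0, 0),
        O3 = 1.5 * d100,
        C4 = 1.5 * d215,
        C5 = c(0, 0, 1.4),
        C6 = 3.0 * d215)
}

#' Generate a toy ligand
#'
#' `toy_ligand_rigid` has no rotatable bonds; `toy_ligand_flex` adds a
#' two-branch torsion tree. Both span hydrophobic carbon, donor nitrogen
#' and acceptor oxygen types.
#'
#' @param spec A [fixture_spec()] or kind string.
#' @param seed Seed when `spec` is a string (toy ligands are seed-invariant).
#' @return An `allodeck_ligand`, typed.
#' @export
make_ligand <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- fixture_spec(spec, seed)
  base <- rigid_ligand_coords()
  mk_atoms <- function(xyz, names, elements) {
    tibble::tibble(serial = seq_len(nrow(xyz)), name = names,
                   resname = "LIG", chain = "X", resseq = 1L,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = elements)
  }
  if (spec$kind == "toy_ligand_rigid") {
    atoms <- mk_atoms(base, c("C1", "N2", "H2", "O3", "C4", "C5", "C6"),
                      c("C", "N", "H", "O", "C", "C", "C"))
    lig <- ligand_from_parts(atoms, root = seq_len(nrow(atoms)),
                             torsdof = 0L, ionizable = 2L,
                             source = "fixture:toy_ligand_rigid")
  } else if (spec$kind == "toy_ligand_flex") {
    c6 <- base["C6", ]
    o7 <- c6 + c(-0.5, -0.6, 1.0)               # bonded to C6
    xyz <- rbind(base, O7 = o7)
    atoms <- mk_atoms(xyz,
                      c("C1", "N2", "H2", "O3", "C4", "C5", "C6", "O7"),
                      c("C", "N", "H", "O", "C", "C", "C", "O"))
    branches <- list(
      list(parent_atom = 1L, child_atom = 5L, atoms = 5L,
           parent_branch = 0L),
      list(parent_atom = 5L, child_atom = 7L, atoms = c(7L, 8L),
           parent_branch = 1L))
    lig <- ligand_from_parts(atoms, root = c(1L, 2L, 3L, 4L, 6L),
                             branches = branches, torsdof = 2L,
                             ionizable = 2L,
                             source = "fixture:toy_ligand_flex")
  } else {
    stop("unknown ligand fixture kind '", spec$kind, "'", call. = FALSE)
  }
  # basic amine, protonated at physiological pH: the nitrogen is then a
  # pure donor, so each pocket anchor matches exactly one ligand arm
  protonate_by_pka(assign_dock_types(lig), pka = 9.1)
}

#' Write a fixture to disk with its ground truth
#'
#' Emits `<kind>.pdb` and `<kind>_truth.json` (or `<kind>.pdbqt` for
#' ligands) under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (spec$kind %in% c("toy_ligand_rigid", "toy_ligand_flex")) {
    lig <- make_ligand(spec)
    path <- file.path(dir, paste0(spec$kind, ".pdbqt"))
    write_pdbqt(lig, path)
    return(invisible(c(structure = path)))
  }
  fx <- make_receptor(spec)
  pdb <- file.path(dir, paste0(spec$kind, ".pdb"))
  truth <- file.path(dir, paste0(spec$kind, "_truth.json"))
  write_pdb(fx$structure, pdb)
  tr <- fx$truth
  if (!is.null(tr$planted_pose)) tr$planted_pose <- unname(
    split(tr$planted_pose, row(tr$planted_pose)))
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA)
  invisible(c(structure = pdb, truth = truth))
}

#' Packaged free-energy component tables
#'
#' Returns the four tables shipped with the package: `table1` (docking
#' scores of three modulators across seven candidate sites; one cell is an
#' explicit missing value, never zero), `table2` (five
#' complex MM-PBSA-WSAS rows with internal energy), `table3` (modulator
#' binding energies) and `table4` (orthosteric-agonist binding energies,
#' including the no-modulator control row and the modulator-as-receptor
#' `H*` row).
#'
#' @return A named list of tibbles.
#' @export
packaged_tables <- function() {
  f <- function(name) load_energy_table(
    system.file("extdata", name, package = "allodeck", mustWork = TRUE))
  list(table1 = f("table1_docking_scores.tsv"),
       table2 = f("table2_complex_energies.tsv"),
       table3 = f("table3_am_binding.tsv"),
       table4 = f("table4_agonist_binding.tsv"))
}
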