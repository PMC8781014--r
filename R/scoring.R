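# Five-term empirical pair potential and the nine per-residue
# binding-recognition vectors.
#
# All terms are functions of the surface distance d' = d - (r_i + r_j),
# the center distance minus the two van der Waals radii. Terms are zero
# beyond an 8 A center-distance cutoff.

VINA_WEIGHTS <- c(gauss1 = -0.035579, gauss2 = -0.005156,
                  repulsion = 0.840245, hydrophobic = -0.035069,
                  hbond = -0.587439)
W_ROT <- 0.05846
SCORE_CUTOFF <- 8.0

# van der Waals radii per docking type (Angstrom)
VDW_RADII <- c(C_H = 1.9, C_P = 1.9,
               N_D = 1.8, N_A = 1.8, N_DA = 1.8, N_P = 1.8,
               O_A = 1.7, O_DA = 1.7,
               S = 2.0, P = 2.1,
               F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2, MET = 1.2)

#' Van der Waals radius of a docking type
#'
#' @param dock_type Character vector of docking types.
#' @return Numeric radii in Angstrom.
#' @export
vdw_radius <- function(dock_type) {
  r <- VDW_RADII[dock_type]
  if (anyNA(r)) stop("no van der Waals radius for type '",
                     dock_type[which(is.na(r))[1]], "'", call. = FALSE)
  unname(r)
}

# raw term shapes on surface distance, vectorized
term_gauss1 <- function(dp) exp(-(dp / 0.5)^2)
term_gauss2 <- function(dp) exp(-((dp - 3) / 2)^2)
term_repulsion <- function(dp) ifelse(dp < 0, dp^2, 0)
term_hydrophobic <- function(dp) {
  # 1 inside the favorable plateau (d' <= 0.5), linear ramp to 0 at 1.5
  ifelse(dp <= 0.5, 1, ifelse(dp >= 1.5, 0, 1.5 - dp))
}
term_hbond <- function(dp) {
  # 1 for d' <= -0.7, linear ramp to 0 at d' = 0
  ifelse(dp <= -0.7, 1, ifelse(dp >= 0, 0, dp / -0.7))
}

#' Five scoring terms for one atom pair
#'
#' Evaluates the five-term empirical potential (two attractive gaussians, a
#' quadratic repulsion wall, a hydrophobic ramp and a hydrogen-bond ramp) on
#' the surface distance `distance - (radius_i + radius_j)`. The hydrophobic
#' term is nonzero only when both atoms are hydrophobic; the hydrogen-bond
#' term only for donor-acceptor pairs. All terms vanish beyond the 8 A
#' center-distance cutoff.
#'
#' @param type_i,type_j Docking types of the two atoms.
#' @param distance Center-to-center distance (Angstrom), vectorized.
#' @param radius_i,radius_j Van der Waals radii; default from the types.
#' @return A tibble with columns `gauss1`, `gauss2`, `repulsion`,
#'   `hydrophobic`, `hbond` (dimensionless) and `weighted_sum` (kcal/mol).
#' @export
pair_terms <- function(type_i, type_j, distance,
                       radius_i = vdw_radius(type_i),
                       radius_j = vdw_radius(type_j)) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  if (is.na(VDW_RADII[type_i]) || is.na(VDW_RADII[type_j])) {
    stop("untyped atom in pair_terms", call. = FALSE)
  }
  dp <- distance - (radius_i + radius_j)
  live <- distance <= SCORE_CUTOFF
  g1 <- ifelse(live, term_gauss1(dp), 0)
  g2 <- ifelse(live, term_gauss2(dp), 0)
  rep_ <- ifelse(live, term_repulsion(dp), 0)
  both_phobic <- (type_i %in% HYDROPHOBIC_TYPES) &&
    (type_j %in% HYDROPHOBIC_TYPES)
  da <- ((type_i %in% DONOR_TYPES) && (type_j %in% ACCEPTOR_TYPES)) ||
    ((type_i %in% ACCEPTOR_TYPES) && (type_j %in% DONOR_TYPES))
  ph <- if (both_phobic) ifelse(live, term_hydrophobic(dp), 0) else 0 * dp
  hb <- if (da) ifelse(live, term_hbond(dp), 0) else 0 * dp
  ws <- VINA_WEIGHTS["gauss1"] * g1 + VINA_WEIGHTS["gauss2"] * g2 +
    VINA_WEIGHTS["repulsion"] * rep_ + VINA_WEIGHTS["hydrophobic"] * ph +
    VINA_WEIGHTS["hbond"] * hb
  tibble::tibble(gauss1 = g1, gauss2 = g2, repulsion = rep_,
                 hydrophobic = ph, hbond = hb,
                 weighted_sum = unname(ws))
}

# -- fast scoring core --------------------------------------------------------
# Precomputed receptor/ligand pairing context reused across many evaluations
# (the docking search scores thousands of candidate coordinates).

score_context <- function(receptor, ligand_atoms) {
  check_typed(receptor$atoms, "receptor")
  check_typed(ligand_atoms, "ligand")
  ra <- receptor$atoms[is_heavy(receptor$atoms), ]
  la <- ligand_atoms[is_heavy(ligand_atoms), ]
  ctx <- list(
    rec = ra,
    rec_xyz = coords_matrix(ra),
    rec_r = vdw_radius(ra$dock_type),
    lig_idx = which(is_heavy(ligand_atoms)),
    lig_r = vdw_radius(la$dock_type),
    res_index = ra$res_index)
  m <- nrow(la); n <- nrow(ra)
  ctx$rsum <- outer(ctx$lig_r, ctx$rec_r, `+`)
  ctx$phobic <- outer(la$dock_type %in% HYDROPHOBIC_TYPES,
                      ra$dock_type %in% HYDROPHOBIC_TYPES, `&`)
  ctx$hb <- outer(la$dock_type %in% DONOR_TYPES,
                  ra$dock_type %in% ACCEPTOR_TYPES, `&`) |
    outer(la$dock_type %in% ACCEPTOR_TYPES,
          ra$dock_type %in% DONOR_TYPES, `&`)
  ctx$rec_sq <- rowSums(ctx$rec_xyz^2)
  ctx
}

# all heavy-pair center distances, m x n
pair_dist <- function(ctx, lig_xyz) {
  m <- nrow(lig_xyz)
  d2 <- matrix(rowSums(lig_xyz^2), m, length(ctx$rec_sq)) +
    matrix(ctx$rec_sq, m, length(ctx$rec_sq), byrow = TRUE) -
    2 * lig_xyz %*% t(ctx$rec_xyz)
  sqrt(pmax(d2, 0))
}

# total weighted intermolecular score only (hot path)
score_total <- function(ctx, lig_xyz) {
  d <- pair_dist(ctx, lig_xyz)
  live <- which(d <= SCORE_CUTOFF)
  if (!length(live)) return(0)
  dp <- d[live] - ctx$rsum[live]
  s <- VINA_WEIGHTS["gauss1"] * term_gauss1(dp) +
    VINA_WEIGHTS["gauss2"] * term_gauss2(dp) +
    VINA_WEIGHTS["repulsion"] * term_repulsion(dp)
  ph <- ctx$phobic[live]
  if (any(ph)) s[ph] <- s[ph] +
      VINA_WEIGHTS["hydrophobic"] * term_hydrophobic(dp[ph])
  hb <- ctx$hb[live]
  if (any(hb)) s[hb] <- s[hb] + VINA_WEIGHTS["hbond"] * term_hbond(dp[hb])
  sum(s)
}

#' Score a receptor-ligand complex in score-only mode
#'
#' Evaluates the five-term potential over every receptor-ligand heavy-atom
#' pair within the cutoff and bins the contributions by receptor residue,
#' producing the nine binding-recognition vectors per residue: `gauss`
#' (= gauss1 + gauss2), `gauss1`, `gauss2`, `repulsion`, `steric`
#' (= gauss1 + gauss2 + repulsion), `hbond`, `hydrophobic`, `non_steric`
#' (= hbond + hydrophobic) and `residue_energy` (the weighted total,
#' kcal/mol). Term columns are unweighted; `residue_energy` is weighted, and
#' the residue energies sum exactly to the intermolecular score. The
#' reported `normalized_affinity` divides the intermolecular score by
#' `1 + w_rot * n_rotatable`.
#'
#' @param receptor A typed `allodeck_structure`.
#' @param ligand A typed `allodeck_ligand` (or typed structure) with final
#'   coordinates.
#' @param mode Only `"score_only"` is accepted here; pose search lives in
#'   [dock()].
#' @return An `allodeck_profile`: residue table plus totals.
#' @export
score_complex <- function(receptor, ligand, mode = "score_only") {
  stopifnot(identical(mode, "score_only"))
  n_rot <- if (inherits(ligand, "allodeck_ligand")) ligand$n_rotatable else 0L
  empty <- nrow(receptor$atoms) == 0 || nrow(ligand$atoms) == 0 ||
    !any(is_heavy(receptor$atoms)) || !any(is_heavy(ligand$atoms))
  if (empty) {
    return(new_profile(residue_profile_skeleton(), 0, 0, n_rot))
  }
  ctx <- score_context(receptor, ligand$atoms)
  d <- pair_dist(ctx, coords_matrix(ligand$atoms[ctx$lig_idx, , drop = FALSE]))
  live <- which(d <= SCORE_CUTOFF)
  res_of_pair <- ctx$res_index[(live - 1) %/% nrow(d) + 1]
  if (length(live)) {
    dp <- d[live] - ctx$rsum[live]
    g1 <- term_gauss1(dp); g2 <- term_gauss2(dp); rp <- term_repulsion(dp)
    ph <- ifelse(ctx$phobic[live], term_hydrophobic(dp), 0)
    hb <- ifelse(ctx$hb[live], term_hbond(dp), 0)
    w <- VINA_WEIGHTS["gauss1"] * g1 + VINA_WEIGHTS["gauss2"] * g2 +
      VINA_WEIGHTS["repulsion"] * rp + VINA_WEIGHTS["hydrophobic"] * ph +
      VINA_WEIGHTS["hbond"] * hb
    acc <- tibble::tibble(res_index = res_of_pair, gauss1 = g1, gauss2 = g2,
                          repulsion = rp, hydrophobic = ph, hbond = hb,
                          residue_energy = w)
    per <- dplyr::summarise(dplyr::group_by(acc, .data$res_index),
                            dplyr::across(dplyr::everything(), sum),
                            .groups = "drop")
  } else {
    per <- residue_profile_skeleton()[, c("res_index", "gauss1", "gauss2",
                                          "repulsion", "hydrophobic", "hbond",
                                          "residue_energy")]
  }
  rtab <- residues(receptor)
  per <- dplyr::left_join(rtab[, c("res_index", "res_id")], per,
                          by = "res_index")
  per <- dplyr::mutate(per, dplyr::across(dplyr::where(is.numeric),
                                          ~ ifelse(is.na(.x), 0, .x)))
  per <- dplyr::mutate(per,
    gauss = .data$gauss1 + .data$gauss2,
    steric = .data$gauss1 + .data$gauss2 + .data$repulsion,
    non_steric = .data$hbond + .data$hydrophobic)
  per <- per[, c("res_index", "res_id", "gauss", "gauss1", "gauss2",
                 "repulsion", "steric", "hbond", "hydrophobic", "non_steric",
                 "residue_energy")]
  if (!is.null(receptor$annotations)) {
    per <- dplyr::left_join(per, receptor$annotations, by = "res_id")
  }
  inter <- sum(per$residue_energy)
  new_profile(per, inter, inter / (1 + W_ROT * n_rot), n_rot)
}

residue_profile_skeleton <- function() {
  tibble::tibble(res_index = integer(0), res_id = character(0),
                 gauss = numeric(0), gauss1 = numeric(0), gauss2 = numeric(0),
                 repulsion = numeric(0), steric = numeric(0),
                 hbond = numeric(0), hydrophobic = numeric(0),
                 non_steric = numeric(0), residue_energy = numeric(0))
}

new_profile <- function(residues, intermolecular, normalized, n_rot) {
  x <- list(residues = residues,
            intermolecular_score = intermolecular,
            normalized_affinity = normalized,
            n_rotatable = n_rot)
  class(x) <- "allodeck_profile"
  x
}

#' @export
print.allodeck_profile <- function(x, ...) {
  cat(sprintf(paste0("<allodeck_profile> %d residues with contributions, ",
                     "intermolecular %.3f, affinity %.3f kcal/mol\n"),
              sum(x$residues$residue_energy != 0),
              x$intermolecular_score, x$normalized_affinity))
  invisible(x)
}

#' Rank residues of an energy profile
#'
#' @param profile An `allodeck_profile`.
#' @param k Number of residues to return (most favorable first).
#' @return The top-`k` rows of the residue table sorted by `residue_energy`
#'   ascending, ties broken by residue order.
#' @export
rank_residues <- function(profile, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  r <- profile$residues
  if (nrow(r) == 0) stop("profile is empty", call. = FALSE)
  ord <- order(r$residue_energy, r$res_index)
  head(r[ord, ], k)
}

#' Write a residue energy profile as TSV
#'
#' @param profile An `allodeck_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile$residues, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
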