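# Docking atom types
#
#   C_H  hydrophobic carbon        C_P  polar carbon
#   N_D  donor N   N_A acceptor N  N_DA donor+acceptor N  N_P neither
#   O_A  acceptor O                O_DA donor+acceptor O
#   S, P, F, Cl, Br, I             MET  metal
#   H_P  polar hydrogen            H    apolar hydrogen
#
# Heavy atoms only enter scoring; polar hydrogens are retained solely to
# flag donors.

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
                    Zn = 1.22, Mg = 1.41, Mn = 1.39, Ca = 1.76, Fe = 1.32,
                    Na = 1.66, K = 2.03)

METALS <- c("Zn", "Mg", "Mn", "Ca", "Fe", "Na", "K")

HYDROPHOBIC_TYPES <- c("C_H", "F", "Cl", "Br", "I")
DONOR_TYPES <- c("N_D", "N_DA", "O_DA", "MET")
ACCEPTOR_TYPES <- c("N_A", "N_DA", "O_A", "O_DA")
HEAVY_TYPES <- c("C_H", "C_P", "N_D", "N_A", "N_DA", "N_P",
                 "O_A", "O_DA", "S", "P", "F", "Cl", "Br", "I", "MET")

# covalent-radius bond criterion: d <= r_i + r_j + 0.4 Angstrom
perceive_bonds <- function(atoms) {
  el <- atoms$element
  r <- COVALENT_RADII[el]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop(sprintf("unknown element '%s' (atom serial %d, %s)",
                 el[bad], atoms$serial[bad], atoms$name[bad]), call. = FALSE)
  }
  xyz <- coords_matrix(atoms)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, `+`) + 0.4
  hit <- which(d <= thr & upper.tri(d) & d > 1e-6, arr.ind = TRUE)
  unname(hit)
}

#' Assign docking atom types
#'
#' Gives every atom a docking type from bonded connectivity (perceived with a
#' covalent-radius distance criterion): carbons bonded only to carbon or
#' hydrogen are hydrophobic, otherwise polar; nitrogen and oxygen
#' donor/acceptor flags come from bonded polar hydrogens and valence;
#' hydrogens bonded to N/O/S are polar. Typing must precede scoring.
#'
#' @param x An `allodeck_structure` or `allodeck_ligand`.
#' @return The same object with `dock_type` filled for every atom.
#' @export
assign_dock_types <- function(x) {
  atoms <- x$atoms
  el <- atoms$element
  bonds <- perceive_bonds(atoms)
  n <- nrow(atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  neigh_el <- function(i) el[nb[[i]]]

  type <- character(n)
  # hydrogens first: polar when bonded to N/O/S
  is_h <- el == "H"
  for (i in which(is_h)) {
    type[i] <- if (any(neigh_el(i) %in% c("N", "O", "S"))) "H_P" else "H"
  }
  for (i in which(!is_h)) {
    e <- el[i]
    ne <- neigh_el(i)
    heavy_ne <- ne[ne != "H"]
    has_h <- any(ne == "H")
    type[i] <- switch(
      e,
      C = if (length(heavy_ne) == 0 || all(heavy_ne == "C")) "C_H" else "C_P",
      N = {
        donor <- has_h
        acceptor <- length(ne) < 4   # no lone pair on 4-coordinate N
        if (donor && acceptor) "N_DA" else if (donor) "N_D"
        else if (acceptor) "N_A" else "N_P"
      },
      O = if (has_h) "O_DA" else "O_A",
      S = "S", P = "P",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      if (e %in% METALS) "MET"
      else stop(sprintf("unknown element '%s' (atom serial %d, %s)",
                        e, atoms$serial[i], atoms$name[i]), call. = FALSE))
  }
  x$atoms$dock_type <- type
  x
}

is_heavy <- function(atoms) atoms$element != "H"

check_typed <- function(atoms, what) {
  untyped <- is_heavy(atoms) & (is.na(atoms$dock_type) |
                                  !(atoms$dock_type %in% HEAVY_TYPES))
  if (any(untyped)) {
    i <- which(untyped)[1]
    stop(sprintf("untyped heavy atom in %s (serial %d, %s); run assign_dock_types() first",
                 what, atoms$serial[i], atoms$name[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Protonate a ligand by its pKa
#'
#' Applies the rule that the ligand's designated ionizable nitrogen is
#' protonated when its pKa is greater than or equal to the working pH
#' (7.4 by default). When protonation fires, the site's docking type becomes
#' a donor nitrogen and its formal charge +1. The designated site is
#' interpreted as the ligand's basic amine-like nitrogen by default; set
#' `site_kind = "amide"` to record the literal amide reading instead (the
#' rule itself is identical, only the annotation differs).
#'
#' @param ligand An `allodeck_ligand` with an `ionizable` atom index (or
#'   none, in which case only the `protonated` flag is set).
#' @param pka Ligand pKa; defaults to the value stored on the ligand.
#' @param ph Working pH (default 7.4).
#' @param site_kind Either `"amine"` (default) or `"amide"`; recorded on the
#'   returned ligand.
#' @return The ligand with `protonated` set, and the ionizable nitrogen
#'   retyped/charged when protonated.
#' @export
protonate_by_pka <- function(ligand, pka = ligand$pka, ph = 7.4,
                             site_kind = c("amine", "amide")) {
  site_kind <- match.arg(site_kind)
  if (is.null(pka) || length(pka) == 0 || is.na(pka)) {
    stop("no pKa supplied for protonation rule", call. = FALSE)
  }
  ligand$pka <- pka
  ligand$protonated <- pka >= ph      # boundary: >= by definition
  ligand$site_kind <- site_kind
  i <- ligand$ionizable
  if (isTRUE(ligand$protonated) && !is.na(i)) {
    if (ligand$atoms$element[i] != "N") {
      stop("designated ionizable site is not a nitrogen", call. = FALSE)
    }
    ligand$atoms$dock_type[i] <- "N_D"
    ligand$atoms$charge[i] <- 1
  }
  ligand
}
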