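# -- atom table ---------------------------------------------------------------

ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
               "icode", "x", "y", "z", "charge", "element", "dock_type")

new_atom_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("serial", "name", "resname", "chain", "resseq",
                  "x", "y", "z", "element") %in% names(df)))
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"altloc" %in% names(df)) df$altloc <- ""
  if (!"charge" %in% names(df)) df$charge <- NA_real_
  if (!"dock_type" %in% names(df)) df$dock_type <- NA_character_
  df[ATOM_COLS]
}

# residue index in order of first appearance; the residue identity key is
# (chain, resseq, icode) -- author numbering kept verbatim
add_res_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  atoms$res_index <- match(key, unique(key))
  atoms
}

res_id_string <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resname, atoms$resseq,
         ifelse(atoms$icode == "", "", atoms$icode))
}

#' Create a typed receptor structure
#'
#' Wraps an atom table into an `allodeck_structure`, the receptor object all
#' scoring and site-detection stages consume. Atoms are grouped into residues
#' by `(chain, resseq, icode)` in order of first appearance.
#'
#' @param atoms A data frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resseq`, `x`, `y`, `z`, `element` (and optionally `icode`,
#'   `charge`, `dock_type`).
#' @param annotations Optional per-residue label table (e.g.
#'   Ballesteros-Weinstein tags) with columns `res_id` and `label`; carried as
#'   metadata, never used in computation.
#' @param source Character tag recording where the structure came from.
#' @return An `allodeck_structure` object.
#' @export
structure_from_atoms <- function(atoms, annotations = NULL, source = "memory") {
  atoms <- add_res_index(new_atom_tbl(atoms))
  x <- list(atoms = atoms, annotations = annotations, source = source)
  class(x) <- "allodeck_structure"
  x
}

#' @export
print.allodeck_structure <- function(x, ...) {
  cat(sprintf("<allodeck_structure> %d atoms, %d residues (%s)\n",
              nrow(x$atoms), max(x$atoms$res_index), x$source))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure An `allodeck_structure`.
#' @return A tibble with one row per residue: `res_index`, `res_id`, `chain`,
#'   `resname`, `resseq`, `icode`, `n_atoms`.
#' @export
residues <- function(structure) {
  a <- structure$atoms
  a$res_id <- res_id_string(a)
  out <- dplyr::summarise(
    dplyr::group_by(a, .data$res_index),
    res_id = .data$res_id[1], chain = .data$chain[1],
    resname = .data$resname[1], resseq = .data$resseq[1],
    icode = .data$icode[1], n_atoms = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$res_index)
}

# -- fixed-column ATOM/HETATM parsing ----------------------------------------
# One parser shared by PDB and PDBQT; PDBQT adds a partial-charge field
# (cols 67-76) and an AutoDock-style type tag (cols 78-79) at record end,
# kept as opaque text in `pdbqt_type`.

substr_trim <- function(lines, a, b) trimws(substr(lines, a, b))

parse_atom_lines <- function(lines, lineno, pdbqt = FALSE) {
  num <- function(a, b, what) {
    s <- substr_trim(lines, a, b)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & s != "")
    if (length(bad)) {
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   lineno[bad[1]], what, s[bad[1]]), call. = FALSE)
    }
    v
  }
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: missing coordinate", lineno[bad[1]]),
         call. = FALSE)
  }
  element <- substr_trim(lines, 77, 78)
  name <- substr_trim(lines, 13, 16)
  pdbqt_type <- if (pdbqt) substr_trim(lines, 78, 79) else ""
  if (pdbqt) element <- element_from_pdbqt_type(pdbqt_type, name)
  element <- ifelse(element == "", element_from_name(name), element)
  charge <- if (pdbqt) num(67, 76, "partial charge") else NA_real_
  tibble::tibble(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    altloc = substr_trim(lines, 17, 17),
    resname = substr_trim(lines, 18, 21),
    chain = substr_trim(lines, 22, 22),
    resseq = as.integer(num(23, 26, "residue number")),
    icode = substr_trim(lines, 27, 27),
    x = x, y = y, z = z,
    charge = charge,
    element = element,
    dock_type = NA_character_,
    pdbqt_type = pdbqt_type)
}

# AutoDock-family type tags map back to elements; unknown tags fall through
# to name-based deduction
element_from_pdbqt_type <- function(type, name) {
  map <- c(C = "C", A = "C", N = "N", NA. = "N", OA = "O", O = "O", S = "S",
           SA = "S", P = "P", H = "H", HD = "H", HS = "H", F = "F",
           Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I",
           Zn = "Zn", ZN = "Zn", Mg = "Mg", MG = "Mg", Mn = "Mn",
           Ca = "Ca", CA = "Ca", Fe = "Fe", FE = "Fe")
  key <- ifelse(type == "NA", "NA.", type)
  out <- unname(map[key])
  ifelse(is.na(out) | type == "", "", out)
}

element_from_name <- function(name) {
  two <- c("CL", "BR", "ZN", "MG", "MN", "FE", "NA", "CA")
  first2 <- toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 2))
  stripped <- gsub("^[0-9]+", "", name)
  one <- toupper(substr(stripped, 1, 1))
  ifelse(first2 %in% two & nchar(gsub("[^A-Za-z]", "", name)) > 1,
         paste0(substr(first2, 1, 1), tolower(substr(first2, 2, 2))),
         one)
}

#' Read a PDB file
#'
#' Parses `ATOM`/`HETATM` records in file order and groups atoms into
#' residues. No docking atom types are assigned; see [assign_dock_types()].
#'
#' @param path Path to a PDB file.
#' @return An `allodeck_structure`.
#' @export
read_pdb <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM") |
                  trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(keep)) stop("no ATOM records in '", path, "'", call. = FALSE)
  atoms <- parse_atom_lines(lines[keep], keep, pdbqt = FALSE)
  atoms$pdbqt_type <- NULL
  structure_from_atoms(atoms, source = path)
}

format_atom_line <- function(a, pdbqt = FALSE) {
  nm <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
               paste0(" ", a$name), a$name)
  base <- sprintf("ATOM  %5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                  a$serial %% 100000L, nm, a$altloc, a$resname, a$chain,
                  a$resseq %% 10000L, a$icode, a$x, a$y, a$z, 1, 0)
  if (pdbqt) {
    q <- ifelse(is.na(a$charge), 0, a$charge)
    t <- dock_type_to_pdbqt(a$dock_type, a$element)
    sprintf("%s    %6.3f %-2s", base, q, t)
  } else {
    sprintf("%s          %2s", base, a$element)
  }
}

#' Write a structure to a PDB file
#'
#' @param structure An `allodeck_structure` or `allodeck_ligand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- c(format_atom_line(structure$atoms, pdbqt = FALSE), "END")
  writeLines(lines, path)
  invisible(path)
}

# -- PDBQT --------------------------------------------------------------------

#' Read a PDBQT file
#'
#' Files containing a `ROOT` record are parsed as ligands with a torsion tree
#' mirroring the `BRANCH` nesting; otherwise the file is read as a rigid
#' receptor. `n_rotatable` is taken from `TORSDOF` when present, else the
#' branch count.
#'
#' @param path Path to a PDBQT file (AutoDock-family dialect).
#' @return An `allodeck_ligand` when the file has a torsion tree, else an
#'   `allodeck_structure`.
#' @export
read_pdbqt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  if (!any(rec == "ROOT")) {
    keep <- which(rec %in% c("ATOM", "HETATM"))
    if (!length(keep)) stop("no ATOM records in '", path, "'", call. = FALSE)
    atoms <- parse_atom_lines(lines[keep], keep, pdbqt = TRUE)
    st <- structure_from_atoms(atoms, source = path)
    st$atoms$dock_type <- dock_type_from_pdbqt(atoms$pdbqt_type)
    return(st)
  }

  atoms_list <- list()
  # branches: parent_atom/child_atom are serials while parsing, indices after
  branches <- list()
  stack <- integer(0)          # open branch ids; 0 = root scope
  torsdof <- NA_integer_
  in_root_seen <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r %in% c("ATOM", "HETATM")) {
      a <- parse_atom_lines(lines[i], i, pdbqt = TRUE)
      a$branch <- if (length(stack)) stack[length(stack)] else 0L
      atoms_list[[length(atoms_list) + 1L]] <- a
    } else if (r == "ROOT") {
      in_root_seen <- TRUE
    } else if (r == "BRANCH") {
      f <- as.integer(strsplit(trimws(substr(lines[i], 7, 80)), "\\s+")[[1]])
      if (length(f) != 2 || anyNA(f)) {
        stop(sprintf("parse error at line %d: malformed BRANCH record", i),
             call. = FALSE)
      }
      branches[[length(branches) + 1L]] <- list(
        parent_atom = f[1], child_atom = f[2],
        parent_branch = if (length(stack)) stack[length(stack)] else 0L)
      stack <- c(stack, length(branches))
    } else if (r == "ENDBRA" || startsWith(lines[i], "ENDBRANCH")) {
      if (!length(stack)) {
        stop(sprintf("parse error at line %d: ENDBRANCH without open BRANCH", i),
             call. = FALSE)
      }
      stack <- stack[-length(stack)]
    } else if (r == "TORSDO" || startsWith(lines[i], "TORSDOF")) {
      torsdof <- as.integer(trimws(substr(lines[i], 8, 80)))
    }
  }
  if (length(stack)) stop("unbalanced BRANCH nesting in '", path, "'",
                          call. = FALSE)
  if (!in_root_seen || !length(atoms_list)) {
    stop("no ATOM records in '", path, "'", call. = FALSE)
  }
  atoms <- dplyr::bind_rows(atoms_list)
  branch_of <- atoms$branch
  atoms$branch <- NULL
  # serials -> row indices
  for (b in seq_along(branches)) {
    branches[[b]]$parent_atom <- match(branches[[b]]$parent_atom, atoms$serial)
    branches[[b]]$child_atom <- match(branches[[b]]$child_atom, atoms$serial)
    branches[[b]]$atoms <- which(branch_of == b)
    if (is.na(branches[[b]]$parent_atom) || is.na(branches[[b]]$child_atom)) {
      stop("BRANCH record references unknown atom serial in '", path, "'",
           call. = FALSE)
    }
  }
  lig <- ligand_from_parts(atoms, root = which(branch_of == 0L),
                           branches = branches, torsdof = torsdof,
                           source = path)
  lig$atoms$dock_type <- dock_type_from_pdbqt(atoms$pdbqt_type)
  lig
}

#' Create a ligand model
#'
#' @param atoms Atom table (see [structure_from_atoms()]).
#' @param root Integer indices of the rigid root fragment.
#' @param branches List of branches, each
#'   `list(parent_atom, child_atom, atoms, parent_branch)` with atom indices
#'   into `atoms`; `parent_branch` 0 means the branch hangs off the root.
#' @param torsdof Declared torsional degrees of freedom (optional).
#' @param pka Optional ligand pKa.
#' @param ionizable Optional index of the designated ionizable nitrogen.
#' @param source Provenance tag.
#' @return An `allodeck_ligand`.
#' @export
ligand_from_parts <- function(atoms, root, branches = list(),
                              torsdof = NA_integer_, pka = NULL,
                              ionizable = NA_integer_, source = "memory") {
  atoms <- add_res_index(new_atom_tbl(atoms))
  covered <- sort(c(root, unlist(lapply(branches, `[[`, "atoms"))))
  if (!identical(covered, seq_len(nrow(atoms)))) {
    stop("torsion tree must span all atoms exactly once", call. = FALSE)
  }
  x <- list(atoms = atoms, root = root, branches = branches,
            n_rotatable = if (!is.na(torsdof)) torsdof else length(branches),
            torsdof = torsdof, pka = pka, protonated = FALSE,
            ionizable = ionizable, source = source)
  class(x) <- "allodeck_ligand"
  x
}

#' @export
print.allodeck_ligand <- function(x, ...) {
  cat(sprintf("<allodeck_ligand> %d atoms, %d rotatable bonds%s\n",
              nrow(x$atoms), x$n_rotatable,
              if (isTRUE(x$protonated)) ", protonated" else ""))
  invisible(x)
}

# atoms moved when branch i rotates: its own atoms plus all descendants
branch_subtree_atoms <- function(ligand, i) {
  kids <- which(vapply(ligand$branches, `[[`, 0L, "parent_branch") == i)
  out <- ligand$branches[[i]]$atoms
  for (k in kids) out <- c(out, branch_subtree_atoms(ligand, k))
  out
}

dock_type_to_pdbqt <- function(dock_type, element) {
  out <- dplyr::case_when(
    dock_type == "C_H" ~ "C", dock_type == "C_P" ~ "C",
    dock_type %in% c("N_D", "N_DA") ~ "N",
    dock_type == "N_A" ~ "NA", dock_type == "N_P" ~ "N",
    dock_type == "O_A" ~ "OA", dock_type == "O_DA" ~ "OA",
    dock_type == "H_P" ~ "HD",
    dock_type %in% c("S", "P", "F", "Cl", "Br", "I") ~ dock_type,
    dock_type == "MET" ~ element,
    TRUE ~ element)
  ifelse(is.na(dock_type), element, out)
}

dock_type_from_pdbqt <- function(type) {
  dplyr::case_when(
    type %in% c("C", "A") ~ "C_H",        # refined by assign_dock_types
    type == "NA" ~ "N_A", type == "N" ~ "N_P",
    type %in% c("OA", "O") ~ "O_A",
    type == "HD" ~ "H_P", type == "H" ~ "H",
    type %in% c("S", "SA") ~ "S", type == "P" ~ "P",
    type %in% c("F") ~ "F", type %in% c("Cl", "CL") ~ "Cl",
    type %in% c("Br", "BR") ~ "Br", type == "I" ~ "I",
    type == "" ~ NA_character_,
    TRUE ~ "MET")
}

write_branch <- function(lig, b_id, lines) {
  b <- lig$branches[[b_id]]
  lines <- c(lines, sprintf("BRANCH %3d %3d",
                            lig$atoms$serial[b$parent_atom],
                            lig$atoms$serial[b$child_atom]))
  lines <- c(lines, format_atom_line(lig$atoms[b$atoms, ], pdbqt = TRUE))
  kids <- which(vapply(lig$branches, `[[`, 0L, "parent_branch") == b_id)
  for (k in kids) lines <- write_branch(lig, k, lines)
  c(lines, sprintf("ENDBRANCH %3d %3d",
                   lig$atoms$serial[b$parent_atom],
                   lig$atoms$serial[b$child_atom]))
}

#' Write a structure or ligand to PDBQT
#'
#' Ligands are serialized with their `ROOT`/`BRANCH` torsion tree and a
#' `TORSDOF` record; receptors as plain rigid records.
#'
#' @param x An `allodeck_structure` or `allodeck_ligand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(x, path) {
  if (inherits(x, "allodeck_ligand")) {
    lines <- "ROOT"
    lines <- c(lines, format_atom_line(x$atoms[x$root, ], pdbqt = TRUE))
    lines <- c(lines, "ENDROOT")
    top <- which(vapply(x$branches, `[[`, 0L, "parent_branch") == 0L)
    for (b in top) lines <- write_branch(x, b, lines)
    lines <- c(lines, sprintf("TORSDOF %d", x$n_rotatable))
  } else {
    lines <- c(format_atom_line(x$atoms, pdbqt = TRUE), "END")
  }
  writeLines(lines, path)
  invisible(path)
}

coords_matrix <- function(x) {
  a <- if (is.data.frame(x)) x else x$atoms
  cbind(a$x, a$y, a$z)
}
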