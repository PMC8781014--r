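test_that("generated receptors round-trip through PDB unchanged", {
  fx <- fx_sphere()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(fx$structure$atoms))
  expect_equal(max(back$atoms$res_index), max(fx$structure$atoms$res_index))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(fx$structure$atoms[, c("x", "y", "z")]))),
            1e-3)
  # residue grouping is stable under a second round trip
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, path2)
  back2 <- read_pdb(path2)
  expect_identical(back2$atoms$res_index, back$atoms$res_index)
})

test_that("an independent PDB reader agrees on the written file", {
  skip_if_not_installed("bio3d")
  fx <- fx_sphere()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$structure, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ref$atom), nrow(fx$structure$atoms))
  expect_equal(ref$atom$x, fx$structure$atoms$x, tolerance = 1e-3)
  expect_equal(ref$atom$resno, fx$structure$atoms$resseq)
})

test_that("PDB parse errors are specific", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), empty)
  expect_error(read_pdb(empty), "no ATOM records")

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      10.000  xx.000  10.000  1.00  0.00           C"),
    bad)
  expect_error(read_pdb(bad), "line 2")
})

test_that("PDBQT ligands mirror BRANCH nesting and count torsions", {
  flex <- fx_lig_flex()
  expect_equal(flex$n_rotatable, 2L)
  expect_length(flex$branches, 2L)

  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(flex, path)
  back <- read_pdbqt(path)
  expect_s3_class(back, "allodeck_ligand")
  expect_equal(back$n_rotatable, 2L)
  expect_equal(nrow(back$atoms), nrow(flex$atoms))
  # identical tree topology: axes and nesting
  topo <- function(l) lapply(l$branches, function(b) {
    c(l$atoms$serial[b$parent_atom], l$atoms$serial[b$child_atom],
      b$parent_branch)
  })
  expect_identical(topo(back), topo(flex))

  rigid <- fx_lig_rigid()
  expect_equal(rigid$n_rotatable, 0L)
  p2 <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(rigid, p2)
  expect_equal(read_pdbqt(p2)$n_rotatable, 0L)
})

test_that("receptor PDBQT files are parsed as rigid structures", {
  fx <- fx_sphere()
  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(fx$typed, path)
  back <- read_pdbqt(path)
  expect_s3_class(back, "allodeck_structure")
  expect_equal(nrow(back$atoms), nrow(fx$typed$atoms))
})

test_that("unbalanced BRANCH nesting is a structural parse error", {
  bad <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "ROOT",
    "ATOM      1  C1  LIG X   1       0.000   0.000   0.000  0.00  0.00     0.000 C ",
    "ENDROOT",
    "BRANCH   1   2",
    "ATOM      2  C2  LIG X   1       1.500   0.000   0.000  0.00  0.00     0.000 C ",
    "TORSDOF 1"), bad)
  expect_error(read_pdbqt(bad), "unbalanced BRANCH")
})

test_that("docking types follow bonded environment", {
  # methane-like fragment: carbon with only hydrogens
  methane <- structure_from_atoms(tibble::tibble(
    serial = 1:2, name = c("C1", "H1"), resname = "LIG", chain = "X",
    resseq = 1L, x = c(0, 1.0), y = 0, z = 0, element = c("C", "H")))
  expect_equal(assign_dock_types(methane)$atoms$dock_type[1], "C_H")

  # carbonyl oxygen: no attached hydrogen -> acceptor only
  carbonyl <- structure_from_atoms(tibble::tibble(
    serial = 1:2, name = c("C1", "O1"), resname = "LIG", chain = "X",
    resseq = 1L, x = c(0, 1.23), y = 0, z = 0, element = c("C", "O")))
  expect_equal(assign_dock_types(carbonyl)$atoms$dock_type[2], "O_A")

  # hydroxyl oxygen: polar hydrogen attached -> donor and acceptor
  hydroxyl <- structure_from_atoms(tibble::tibble(
    serial = 1:3, name = c("C1", "O1", "HO1"), resname = "LIG", chain = "X",
    resseq = 1L, x = c(0, 1.4, 2.3), y = 0, z = 0,
    element = c("C", "O", "H")))
  typed <- assign_dock_types(hydroxyl)
  expect_equal(typed$atoms$dock_type[2], "O_DA")
  expect_equal(typed$atoms$dock_type[3], "H_P")
  # the carbon bonded to the heteroatom is polar
  expect_equal(typed$atoms$dock_type[1], "C_P")

  bad <- structure_from_atoms(tibble::tibble(
    serial = 1L, name = "Q1", resname = "LIG", chain = "X", resseq = 1L,
    x = 0, y = 0, z = 0, element = "Qq"))
  expect_error(assign_dock_types(bad), "unknown element")
})

test_that("typing is total on every fixture", {
  for (st in list(fx_sphere()$typed,
                  assign_dock_types(fx_solid()$structure),
                  fx_lig_rigid(), fx_lig_flex())) {
    atoms <- st$atoms
    heavy <- atoms[atoms$element != "H", ]
    expect_false(any(is.na(heavy$dock_type)))
  }
})

test_that("the pKa protonation rule uses a >= boundary", {
  lig <- fx_lig_rigid()
  lig$protonated <- FALSE
  expect_true(protonate_by_pka(lig, pka = 9.1, ph = 7.4)$protonated)
  expect_false(protonate_by_pka(lig, pka = 5.0, ph = 7.4)$protonated)
  # boundary case: equality protonates
  expect_true(protonate_by_pka(lig, pka = 7.4, ph = 7.4)$protonated)

  p <- protonate_by_pka(lig, pka = 9.1)
  expect_equal(p$atoms$dock_type[p$ionizable], "N_D")
  expect_equal(p$atoms$charge[p$ionizable], 1)

  lig$pka <- NULL
  expect_error(protonate_by_pka(lig), "no pKa")
})

test_that("torsion rotation moves only the branch subtree", {
  flex <- fx_lig_flex()
  base <- allodeck:::apply_torsions(flex, c(0, 0))
  # rotate only the nested branch: root and first-branch atoms bit-identical
  rot2 <- allodeck:::apply_torsions(flex, c(0, 1.2))
  moved2 <- allodeck:::branch_subtree_atoms(flex, 2L)
  expect_identical(base[-moved2, ], rot2[-moved2, ])
  expect_gt(max(abs(base[moved2, ] - rot2[moved2, ])), 0.1)
  # rotating the outer branch leaves the root fixed
  rot1 <- allodeck:::apply_torsions(flex, c(0.9, 0))
  expect_identical(base[flex$root, ], rot1[flex$root, ])
})
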