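test_that("pair terms take their boundary values", {
  r2 <- vdw_radius("C_H") * 2
  # surface contact (d' = 0): first gaussian at its maximum, no repulsion
  t0 <- pair_terms("C_H", "C_H", distance = r2)
  expect_equal(t0$gauss1, 1.0)
  expect_equal(t0$repulsion, 0)
  expect_equal(t0$hydrophobic, 1.0)   # plateau extends to d' = 0.5

  # beyond the cutoff every term is exactly zero
  tc <- pair_terms("C_H", "O_A", distance = 9)
  expect_true(all(tc[1, 1:5] == 0))
  expect_equal(tc$weighted_sum, 0)

  # hydrophobic plateau at d' = 0.2 (both atoms hydrophobic)
  tp <- pair_terms("C_H", "C_H", distance = r2 + 0.2)
  expect_equal(tp$hydrophobic, 1.0)
  # and the ramp midpoint at d' = 1.0
  expect_equal(pair_terms("C_H", "C_H", distance = r2 + 1.0)$hydrophobic, 0.5)

  # hydrogen bond only for donor-acceptor pairs; ramp value at d' = -0.35
  rs <- vdw_radius("N_D") + vdw_radius("O_A")
  expect_equal(pair_terms("N_D", "O_A", distance = rs - 0.35)$hbond, 0.5)
  expect_equal(pair_terms("N_D", "N_D", distance = rs - 0.35)$hbond, 0)
  expect_equal(pair_terms("C_H", "O_A", distance = 3)$hbond, 0)

  expect_error(pair_terms("C_H", "C_H", distance = -1), "distance")
})

test_that("pair terms are symmetric in argument order", {
  types <- c("C_H", "C_P", "N_D", "N_A", "O_A", "O_DA", "S", "MET")
  for (a in types) for (b in types) {
    for (d in c(2.5, 3.4, 4.1, 7.9)) {
      expect_identical(pair_terms(a, b, d), pair_terms(b, a, d))
    }
  }
})

test_that("a single pair reproduces the closed-form weighted sum", {
  rec <- structure_from_atoms(tibble::tibble(
    serial = 1L, name = "CB", resname = "ALA", chain = "A", resseq = 1L,
    x = 0, y = 0, z = 0, element = "C", dock_type = "C_H"))
  lig <- structure_from_atoms(tibble::tibble(
    serial = 1L, name = "C1", resname = "LIG", chain = "X", resseq = 1L,
    x = 4.2, y = 0, z = 0, element = "C", dock_type = "C_H"))
  prof <- score_complex(rec, lig)
  # independent closed form, written out term by term
  dp <- 4.2 - 3.8
  expected <- -0.035579 * exp(-(dp / 0.5)^2) +
    -0.005156 * exp(-((dp - 3) / 2)^2) +
    -0.035069 * 1.0                      # hydrophobic plateau, d' <= 0.5
  expect_equal(prof$residues$residue_energy, expected, tolerance = 1e-12)
  expect_equal(prof$intermolecular_score, expected, tolerance = 1e-12)
})

test_that("distant or empty inputs give zero-energy profiles", {
  fx <- fx_sphere()
  lig <- fx_lig_rigid()
  far <- lig
  far$atoms$x <- far$atoms$x + 100
  prof <- score_complex(fx$typed, far)
  expect_equal(prof$intermolecular_score, 0)
  expect_true(all(prof$residues$residue_energy == 0))

  empty <- structure_from_atoms(tibble::tibble(
    serial = integer(0), name = character(0), resname = character(0),
    chain = character(0), resseq = integer(0), x = numeric(0),
    y = numeric(0), z = numeric(0), element = character(0)))
  prof0 <- score_complex(empty, lig)
  expect_equal(nrow(prof0$residues), 0)
  expect_equal(prof0$intermolecular_score, 0)
})

test_that("decomposition conserves the intermolecular score and its identities", {
  fx <- fx_sphere()
  lig <- lig_at(fx_lig_rigid(), fx$truth$planted_pose)
  prof <- score_complex(fx$typed, lig)
  r <- prof$residues
  expect_lt(abs(sum(r$residue_energy) - prof$intermolecular_score), 1e-6)
  expect_equal(r$gauss, r$gauss1 + r$gauss2, tolerance = 1e-9)
  expect_equal(r$steric, r$gauss1 + r$gauss2 + r$repulsion, tolerance = 1e-9)
  expect_equal(r$non_steric, r$hbond + r$hydrophobic, tolerance = 1e-9)
  # the rigid ligand has no rotatable bonds, so no normalization applies
  expect_equal(prof$normalized_affinity, prof$intermolecular_score)
})

test_that("rotatable bonds scale the reported affinity only", {
  fx <- fx_sphere()
  flex <- lig_at(fx_lig_flex(),
                 rbind(fx$truth$planted_pose,
                       O7 = fx$truth$planted_pose["C6", ] + c(-0.5, -0.6, 1)))
  prof <- score_complex(fx$typed, flex)
  expect_equal(prof$normalized_affinity,
               prof$intermolecular_score / (1 + 0.05846 * 2))
  expect_lt(abs(sum(prof$residues$residue_energy) -
                  prof$intermolecular_score), 1e-6)
})

test_that("scoring equals brute-force pair enumeration on random complexes", {
  rec_atoms <- random_atoms(500, n_res = 60, seed = 11)
  lig_atoms <- random_atoms(50, n_res = 1, seed = 12)
  rec <- structure_from_atoms(rec_atoms)
  lig <- structure_from_atoms(lig_atoms)
  prof <- score_complex(rec, lig)
  ora <- oracle_score(rec_atoms, lig_atoms)
  expect_equal(prof$intermolecular_score, ora$total, tolerance = 1e-9)
  per <- prof$residues[prof$residues$residue_energy != 0, ]
  got <- setNames(per$residue_energy, as.character(sort(unique(
    rec_atoms$resseq))[per$res_index]))
  common <- intersect(names(got), names(ora$per_res))
  expect_equal(got[common], ora$per_res[common], tolerance = 1e-9)
})

test_that("scores are invariant under rigid motion of the whole complex", {
  fx <- fx_sphere()
  lig <- lig_at(fx_lig_rigid(), fx$truth$planted_pose)
  before <- score_complex(fx$typed, lig)

  q <- allodeck:::quat_normalize(c(0.9, 0.2, -0.35, 0.15))
  r <- allodeck:::quat_to_rotmat(q)
  shift <- c(5.5, -3.2, 11)
  move <- function(obj) {
    xyz <- cbind(obj$atoms$x, obj$atoms$y, obj$atoms$z) %*% t(r)
    obj$atoms$x <- xyz[, 1] + shift[1]
    obj$atoms$y <- xyz[, 2] + shift[2]
    obj$atoms$z <- xyz[, 3] + shift[3]
    obj
  }
  after <- score_complex(move(fx$typed), move(lig))
  expect_equal(after$intermolecular_score, before$intermolecular_score,
               tolerance = 1e-9)
  expect_equal(after$residues$residue_energy,
               before$residues$residue_energy, tolerance = 1e-9)
})

test_that("residue ranking sorts ascending with stable ties", {
  fake <- allodeck:::new_profile(
    tibble::tibble(res_index = 1:3, res_id = c("A", "B", "C"),
                   gauss = 0, gauss1 = 0, gauss2 = 0, repulsion = 0,
                   steric = 0, hbond = 0, hydrophobic = 0,
                   non_steric = 0,
                   residue_energy = c(-1.2, -0.3, 0.1)),
    -1.4, -1.4, 0L)
  expect_equal(rank_residues(fake, 2)$res_id, c("A", "B"))
  expect_equal(rank_residues(fake, 1)$res_id, "A")
  expect_error(rank_residues(fake, 0), "positive")

  # oracle sort on a random 50-residue profile
  set.seed(42)
  e <- round(rnorm(50), 2)   # rounding forces ties
  fake2 <- allodeck:::new_profile(
    tibble::tibble(res_index = 1:50, res_id = sprintf("R%02d", 1:50),
                   gauss = 0, gauss1 = 0, gauss2 = 0, repulsion = 0,
                   steric = 0, hbond = 0, hydrophobic = 0, non_steric = 0,
                   residue_energy = e),
    sum(e), sum(e), 0L)
  expect_equal(rank_residues(fake2, 50)$res_id,
               sprintf("R%02d", order(e, 1:50)))
})

test_that("profiles tidy, summarize and plot", {
  fx <- fx_sphere()
  prof <- score_complex(fx$typed, lig_at(fx_lig_rigid(),
                                         fx$truth$planted_pose))
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("res_id", "residue_energy") %in% names(td)))
  gl <- glance(prof)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$normalized_affinity, 0)
  p <- autoplot(prof, k = 5)
  expect_s3_class(p, "ggplot")
})
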