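# memoized fixtures: generation (and the planted-pose refinement inside
# the sphere_pocket generator) is deterministic but not free, so each kind
# is built once per test run
.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (!exists(key, .fx_cache)) assign(key, builder(), .fx_cache)
  get(key, .fx_cache)
}

fx_sphere <- function() fx_get("sphere", function() {
  fx <- make_receptor("sphere_pocket", seed = 1)
  fx$typed <- assign_dock_types(fx$structure)
  fx
})

fx_two_pockets <- function() fx_get("two", function() {
  make_receptor("two_pockets", seed = 1)
})

fx_solid <- function() fx_get("solid", function() {
  make_receptor("solid_ball", seed = 1)
})

fx_hinge <- function() fx_get("hinge", function() {
  make_receptor("hinge_dimer", seed = 1)
})

fx_lig_rigid <- function() fx_get("lig_rigid", function() {
  make_ligand("toy_ligand_rigid")
})

fx_lig_flex <- function() fx_get("lig_flex", function() {
  make_ligand("toy_ligand_flex")
})

planted_heavy <- function(fx) {
  p <- fx$truth$planted_pose
  p[rownames(p) != "H2", , drop = FALSE]
}

# ligand with pose coordinates substituted
lig_at <- function(lig, coords) {
  lig$atoms$x <- coords[, 1]
  lig$atoms$y <- coords[, 2]
  lig$atoms$z <- coords[, 3]
  lig
}

# random typed atom table for scoring oracles
random_atoms <- function(n, n_res, seed, spread = 20) {
  set.seed(seed)
  types <- c("C_H", "C_P", "N_D", "N_A", "O_A", "O_DA", "S")
  tibble::tibble(
    serial = seq_len(n),
    name = "X",
    resname = "UNK",
    chain = "A",
    resseq = sort(sample.int(n_res, n, replace = TRUE)),
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread),
    element = "C",
    dock_type = sample(types, n, replace = TRUE))
}

# independent slow oracle: enumerate all pairs through pair_terms()
oracle_score <- function(rec_atoms, lig_atoms) {
  total <- 0
  per_res <- numeric(0)
  for (i in seq_len(nrow(lig_atoms))) {
    for (j in seq_len(nrow(rec_atoms))) {
      d <- sqrt((lig_atoms$x[i] - rec_atoms$x[j])^2 +
                  (lig_atoms$y[i] - rec_atoms$y[j])^2 +
                  (lig_atoms$z[i] - rec_atoms$z[j])^2)
      w <- pair_terms(lig_atoms$dock_type[i], rec_atoms$dock_type[j],
                      d)$weighted_sum
      total <- total + w
      key <- as.character(rec_atoms$resseq[j])
      per_res[key] <- (if (is.na(per_res[key])) 0 else per_res[key]) + w
    }
  }
  list(total = total, per_res = per_res)
}
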