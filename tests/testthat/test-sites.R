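test_that("cavity detection finds exactly the planted voids", {
  pk1 <- detect_cavities(fx_sphere()$structure)
  expect_equal(nrow(pk1), 1)
  truth_cen <- fx_sphere()$truth$cavity_centers[[1]]
  expect_lt(sqrt(sum((c(pk1$cx, pk1$cy, pk1$cz) - truth_cen)^2)), 1.0)
  expect_gt(length(pk1$lining[[1]]), 0)
  # volume accounting: points times spacing cubed
  expect_equal(pk1$volume, nrow(pk1$grid_points[[1]]) * 1.0^3)
  # centroid is the mean of the grid points
  expect_equal(c(pk1$cx, pk1$cy, pk1$cz),
               unname(colMeans(pk1$grid_points[[1]])), tolerance = 1e-9)

  expect_equal(nrow(detect_cavities(fx_solid()$structure)), 0)

  pk2 <- detect_cavities(fx_two_pockets()$structure)
  expect_equal(nrow(pk2), 2)
  cents <- fx_two_pockets()$truth$cavity_centers
  found <- cbind(pk2$cx, pk2$cy, pk2$cz)
  d <- vapply(cents, function(cc) min(sqrt(rowSums(
    sweep(found, 2, cc)^2))), 0)
  expect_true(all(d < 1.0))   # each planted center matched 1:1

  expect_error(detect_cavities(fx_sphere()$structure, spacing = 0), "positive")
})

test_that("refining the grid moves centroids by less than twice the spacing", {
  co <- detect_cavities(fx_sphere()$structure, spacing = 1.0)
  fi <- detect_cavities(fx_sphere()$structure, spacing = 0.5)
  expect_equal(nrow(fi), 1)
  shift <- sqrt(sum((c(co$cx, co$cy, co$cz) - c(fi$cx, fi$cy, fi$cz))^2))
  expect_lt(shift, 2 * 1.0)
})

test_that("the elastic network has six rigid-body modes and a proper correlation matrix", {
  enm <- enm_cross_correlation(fx_hinge()$structure)
  ev <- enm$eigenvalues
  tol <- max(ev) * 1e-8
  expect_equal(sum(ev < tol), 6)
  C <- enm$correlation
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, nrow(C)), tolerance = 1e-9)
  expect_lte(max(abs(C)), 1 + 1e-9)

  tiny <- structure_from_atoms(tibble::tibble(
    serial = 1:2, name = "CB", resname = "ALA", chain = "A", resseq = 1:2,
    x = c(0, 3), y = 0, z = 0, element = "C"))
  expect_error(enm_cross_correlation(tiny), "too few")
})

test_that("the correlation matrix matches a dense pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  enm <- enm_cross_correlation(fx_hinge()$structure)
  nodes <- enm$nodes
  n <- nrow(nodes)
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  hess <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(dist(xyz))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > 15) next
    v <- xyz[j, ] - xyz[i, ]
    blk <- -outer(v, v) / sum(v^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    hess[ii, jj] <- blk; hess[jj, ii] <- blk
    hess[ii, ii] <- hess[ii, ii] - blk; hess[jj, jj] <- hess[jj, jj] - blk
  }
  cov <- MASS::ginv(hess)       # independent pseudo-inverse route
  tr <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tr[i, j] <- sum(diag(cov[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
  }
  oracle <- tr / sqrt(outer(diag(tr), diag(tr)))
  expect_equal(unname(enm$correlation), oracle, tolerance = 1e-6)
})

test_that("motion correlation ranks the orthosteric lobe above the far lobe", {
  fx <- fx_hinge()
  st <- fx$structure
  nodes <- allodeck:::residue_nodes(st)
  left <- nodes$res_id[nodes$x < -10]
  right <- nodes$res_id[nodes$x > 10]
  ortho <- pocket("ortho", centroid = c(-14, 0, 0),
                  lining_residues = left[1:8])
  cands <- dplyr::bind_rows(
    pocket("same_lobe", centroid = c(-12, 2, 0),
           lining_residues = left[9:16]),
    pocket("far_lobe", centroid = c(14, 0, 0),
           lining_residues = right[1:8]))
  z <- motion_correlation_z(st, ortho, cands)
  expect_equal(nrow(z), 2)
  expect_gt(z$raw_correlation[z$id == "same_lobe"],
            z$raw_correlation[z$id == "far_lobe"])
  expect_equal(z$id[1], "same_lobe")     # sorted by z descending
  # z over the candidate set is standardized by construction
  expect_equal(mean(z$z_score), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z$z_score^2)), 1, tolerance = 1e-9)
})

test_that("z-scoring degenerates gracefully and filters strictly", {
  fx <- fx_hinge()
  st <- fx$structure
  nodes <- allodeck:::residue_nodes(st)
  left <- nodes$res_id[nodes$x < -10]
  ortho <- pocket("ortho", centroid = c(-14, 0, 0),
                  lining_residues = left[1:6])
  # identical linings give identical raw correlations: z collapses to 0
  twins <- dplyr::bind_rows(
    pocket("t1", centroid = c(-10, 0, 0), lining_residues = left[7:12]),
    pocket("t2", centroid = c(-10, 2, 0), lining_residues = left[7:12]))
  z <- motion_correlation_z(st, ortho, twins)
  expect_equal(z$z_score, c(0, 0))
  # both fail the strict > 0.5 filter
  expect_equal(nrow(motion_correlation_z(st, ortho, twins, zmin = 0.5)), 0)

  expect_error(motion_correlation_z(st, ortho, twins[1, ]), "two candidate")

  # three-candidate set: strict threshold keeps exactly the high-z one
  right <- nodes$res_id[nodes$x > 10]
  cands3 <- dplyr::bind_rows(
    pocket("near", centroid = c(-12, 2, 0), lining_residues = left[7:14]),
    pocket("far1", centroid = c(14, 0, 0), lining_residues = right[1:8]),
    pocket("far2", centroid = c(13, 2, 0), lining_residues = right[9:16]))
  z3 <- motion_correlation_z(st, ortho, cands3)
  kept <- motion_correlation_z(st, ortho, cands3, zmin = 0.5)
  expect_equal(kept$id, z3$id[z3$z_score > 0.5])
  expect_true("near" %in% kept$id)
})

test_that("consensus keeps sites seen in every complex by enough methods", {
  p <- function(id, cen, method, complex) {
    pocket(id, centroid = cen, method = method, complex = complex)
  }
  # same physical site reported by 3 methods x 2 complexes
  all_same <- dplyr::bind_rows(
    p("a", c(0, 0, 0), "m1", "c1"), p("b", c(1, 0, 0), "m2", "c1"),
    p("c", c(0, 1, 0), "m3", "c1"), p("d", c(0.5, 0.5, 0), "m1", "c2"),
    p("e", c(1, 1, 0), "m2", "c2"), p("f", c(0, 0, 1), "m3", "c2"))
  cons <- consensus_sites(all_same)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_members, 6)

  # one method only, both complexes: dropped by the two-method rule
  single_method <- dplyr::bind_rows(
    p("a", c(0, 0, 0), "m1", "c1"), p("b", c(1, 0, 0), "m1", "c2"))
  expect_equal(nrow(consensus_sites(single_method)), 0)

  # two methods but a single complex among the tags is a precondition error
  expect_error(consensus_sites(dplyr::bind_rows(
    p("a", c(0, 0, 0), "m1", "c1"), p("b", c(1, 0, 0), "m2", "c1"))),
    "two complexes")
})

test_that("consensus reproduces a hand-enumerated outcome and ignores input order", {
  p <- function(id, cen, method, complex) {
    pocket(id, centroid = cen, method = method, complex = complex)
  }
  # seven true sites at well-separated locations, each detected by >= 2
  # methods in both complexes ...
  sites <- lapply(1:7, function(k) c(20 * k, 0, 0))
  rows <- list()
  for (k in 1:7) {
    m2 <- c("m1", "m2", "m3")[1 + (k %% 3)]
    rows[[length(rows) + 1]] <- p(paste0("s", k, "a"), sites[[k]], "m1", "c1")
    rows[[length(rows) + 1]] <- p(paste0("s", k, "b"),
                                  sites[[k]] + c(1, 1, 0), m2, "c2")
    if (m2 == "m1") {
      # method m1 twice is one distinct method; add a second method
      rows[[length(rows) + 1]] <- p(paste0("s", k, "c"),
                                    sites[[k]] + c(0, 1, 1), "m3", "c1")
    }
  }
  # ... plus spoilers: missing a complex, or a single method
  rows[[length(rows) + 1]] <- p("x1", c(300, 0, 0), "m1", "c1")
  rows[[length(rows) + 1]] <- p("x2", c(300, 1, 0), "m2", "c1")
  rows[[length(rows) + 1]] <- p("x3", c(340, 0, 0), "m2", "c1")
  rows[[length(rows) + 1]] <- p("x4", c(340, 1, 0), "m2", "c2")
  pool <- dplyr::bind_rows(rows)

  cons <- consensus_sites(pool)
  expect_equal(nrow(cons), 7)
  # merged centroids sit at the member means of the true sites
  expect_true(all(vapply(sites, function(cc) {
    min(sqrt((cons$cx - cc[1])^2 + (cons$cy - cc[2])^2 +
               (cons$cz - cc[3])^2)) < 2
  }, TRUE)))

  # permuting the pool changes nothing
  set.seed(9)
  for (perm in 1:3) {
    shuffled <- pool[sample.int(nrow(pool)), ]
    again <- consensus_sites(shuffled)
    expect_equal(again[, c("cx", "cy", "cz", "n_members")],
                 cons[, c("cx", "cy", "cz", "n_members")])
  }
})

test_that("pockets survive a JSON round trip", {
  pk <- detect_cavities(fx_sphere()$structure, complex_tag = "cplx1")
  path <- withr::local_tempfile(fileext = ".json")
  write_pockets_json(pk, path)
  back <- read_pockets_json(path)
  expect_equal(nrow(back), nrow(pk))
  expect_equal(back$cx, pk$cx, tolerance = 1e-9)
  expect_equal(back$lining[[1]], pk$lining[[1]])
  expect_equal(back$complex, pk$complex)
})
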