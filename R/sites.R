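# Allosteric-site prediction: geometric cavity detection on a cubic grid
# (protein-solvent-protein scanning with a 1.4 A probe), elastic-network
# motion-correlation z-scoring against a declared orthosteric pocket, and
# the multi-method / multi-complex consensus rule.

PROBE_RADIUS <- 1.4
PSP_DIRECTIONS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

#' Construct a pocket record
#'
#' @param id Pocket identifier.
#' @param centroid 3-vector centroid (Angstrom).
#' @param lining_residues Character vector of residue ids.
#' @param volume Pocket volume (cubic Angstrom).
#' @param ligandability_score Ranking score.
#' @param grid_points Optional matrix of grid points.
#' @param z_score Optional motion-correlation z-score.
#' @param method,complex Source tags for the consensus rule.
#' @return A one-row pocket tibble.
#' @export
pocket <- function(id, centroid, lining_residues = character(0),
                   volume = NA_real_, ligandability_score = NA_real_,
                   grid_points = NULL, z_score = NA_real_,
                   method = NA_character_, complex = NA_character_) {
  tibble::tibble(id = id, cx = centroid[1], cy = centroid[2],
                 cz = centroid[3], volume = volume,
                 ligandability = ligandability_score,
                 z_score = z_score,
                 lining = list(lining_residues),
                 grid_points = list(grid_points),
                 method = method, complex = complex)
}

pocket_centroids <- function(pockets) {
  cbind(pockets$cx, pockets$cy, pockets$cz)
}

# blocked-on-both-sides scan along one lattice direction; occ is a logical
# 3d array, dir an integer step vector
scan_blocked_both <- function(occ, dir) {
  dims <- dim(occ)
  shift1 <- function(a, d) {
    out <- array(FALSE, dims)
    src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    dst <- src
    for (ax in 1:3) {
      if (d[ax] == 1) { dst[[ax]] <- 2:dims[ax]; src[[ax]] <- 1:(dims[ax] - 1) }
      if (d[ax] == -1) { dst[[ax]] <- 1:(dims[ax] - 1); src[[ax]] <- 2:dims[ax] }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  blocked_dir <- function(d) {
    # protein anywhere along +d from each point: b = occ_shift | shift(b)
    b <- array(FALSE, dims)
    for (k in seq_len(max(dims))) {
      nb <- shift1(occ | b, d)
      if (identical(nb, b)) break
      b <- nb
    }
    b
  }
  blocked_dir(dir) & blocked_dir(-dir)
}

#' Detect cavities on a cubic grid
#'
#' Places the structure on a cubic grid, marks grid points within the
#' probe-inflated van der Waals envelope as protein, counts for every
#' solvent point how many of seven scan directions (three axes, four body
#' diagonals) are enclosed by protein on both sides, and keeps points buried
#' in at least `min_buried` directions. Connected components (6-neighbor)
#' above the minimum volume become pockets, ranked by ligandability
#' (volume times mean buriedness fraction, a declared proxy score).
#'
#' @param structure An `allodeck_structure` (typing not required).
#' @param spacing Grid spacing in Angstrom (default 1.0).
#' @param min_buried Minimum number of enclosed scan directions out of 7.
#' @param min_volume Minimum pocket volume in cubic Angstrom.
#' @param contact_distance Atom-to-grid-point distance defining lining
#'   residues.
#' @param complex_tag,method_tag Source tags stored on the pockets.
#' @return A pocket tibble sorted by `ligandability` descending.
#' @export
detect_cavities <- function(structure, spacing = 1.0, min_buried = 5L,
                            min_volume = 8, contact_distance = 4.5,
                            complex_tag = NA_character_,
                            method_tag = "grid_psp") {
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  atoms <- structure$atoms[is_heavy(structure$atoms), ]
  if (!nrow(atoms)) stop("structure is empty", call. = FALSE)
  xyz <- coords_matrix(atoms)
  el_r <- ifelse(atoms$element %in% names(COVALENT_RADII) &
                   atoms$element %in% METALS, 1.2,
                 c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5,
                   Cl = 1.8, Br = 2.0, I = 2.2)[atoms$element])
  el_r[is.na(el_r)] <- 1.8
  pad <- 2 * spacing
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  dims <- c(length(gx), length(gy), length(gz))

  occ <- array(FALSE, dims)
  # mark protein-occupied points atom by atom within its inflated radius
  for (i in seq_len(nrow(xyz))) {
    r <- el_r[i] + PROBE_RADIUS
    ix <- which(abs(gx - xyz[i, 1]) <= r)
    iy <- which(abs(gy - xyz[i, 2]) <= r)
    iz <- which(abs(gz - xyz[i, 3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((gx[ix] - xyz[i, 1])^2, (gy[iy] - xyz[i, 2])^2, `+`),
                (gz[iz] - xyz[i, 3])^2, `+`)
    occ[ix, iy, iz] <- occ[ix, iy, iz] | (d2 <= r^2)
  }

  buried <- array(0L, dims)
  for (k in seq_len(nrow(PSP_DIRECTIONS))) {
    buried <- buried + scan_blocked_both(occ, PSP_DIRECTIONS[k, ])
  }
  pocket_pt <- !occ & buried >= min_buried
  if (!any(pocket_pt)) {
    return(empty_pockets())
  }

  # connected components, 6-neighbor flood fill
  lab <- array(0L, dims)
  nextlab <- 0L
  idx_all <- which(pocket_pt)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, dims)
      for (ax in 1:3) {
        for (dd in c(-1L, 1L)) {
          ni <- ci
          ni[ax] <- ni[ax] + dd
          if (ni[ax] < 1 || ni[ax] > dims[ax]) next
          lin <- ni[1] + dims[1] * (ni[2] - 1L + dims[2] * (ni[3] - 1L))
          if (pocket_pt[lin] && lab[lin] == 0L) {
            lab[lin] <- nextlab
            queue <- c(queue, lin)
          }
        }
      }
    }
  }

  res_tab <- residues(structure)
  a_res_id <- res_id_string(atoms)
  out <- list()
  for (l in seq_len(nextlab)) {
    pts_idx <- which(lab == l)
    if (length(pts_idx) * spacing^3 < min_volume) next
    ai <- arrayInd(pts_idx, dims)
    pts <- cbind(gx[ai[, 1]], gy[ai[, 2]], gz[ai[, 3]])
    vol <- nrow(pts) * spacing^3
    burial_frac <- mean(buried[pts_idx]) / nrow(PSP_DIRECTIONS)
    # lining residues: any atom within contact distance of >= 1 grid point
    mind <- rep(Inf, nrow(xyz))
    for (p in seq_len(nrow(pts))) {
      d2 <- (xyz[, 1] - pts[p, 1])^2 + (xyz[, 2] - pts[p, 2])^2 +
        (xyz[, 3] - pts[p, 3])^2
      mind <- pmin(mind, d2)
    }
    lining <- unique(a_res_id[mind <= contact_distance^2])
    out[[length(out) + 1L]] <- pocket(
      id = sprintf("P%02d", length(out) + 1L),
      centroid = colMeans(pts), lining_residues = lining, volume = vol,
      ligandability_score = vol * burial_frac, grid_points = pts,
      method = method_tag, complex = complex_tag)
  }
  if (!length(out)) return(empty_pockets())
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, dplyr::desc(.data$ligandability))
  res$id <- sprintf("P%02d", seq_len(nrow(res)))
  res
}

empty_pockets <- function() {
  tibble::tibble(id = character(0), cx = numeric(0), cy = numeric(0),
                 cz = numeric(0), volume = numeric(0),
                 ligandability = numeric(0), z_score = numeric(0),
                 lining = list(), grid_points = list(),
                 method = character(0), complex = character(0))
}

# -- elastic network ----------------------------------------------------------

# representative node per residue: CA when present, else residue centroid
residue_nodes <- function(structure) {
  a <- structure$atoms[is_heavy(structure$atoms), ]
  a$res_id <- res_id_string(a)
  per <- dplyr::group_by(a, .data$res_index)
  nodes <- dplyr::summarise(
    per,
    res_id = .data$res_id[1],
    x = if (any(.data$name == "CA")) .data$x[.data$name == "CA"][1]
        else mean(.data$x),
    y = if (any(.data$name == "CA")) .data$y[.data$name == "CA"][1]
        else mean(.data$y),
    z = if (any(.data$name == "CA")) .data$z[.data$name == "CA"][1]
        else mean(.data$z),
    .groups = "drop")
  dplyr::arrange(nodes, .data$res_index)
}

#' Residue motion cross-correlation from an anisotropic elastic network
#'
#' Builds an anisotropic network model on one representative atom per
#' residue (uniform springs within the cutoff), removes the six rigid-body
#' modes by pseudo-inverting the Hessian over the remaining modes, and
#' normalizes the trace of each 3x3 covariance super-element into a
#' cross-correlation matrix with unit diagonal.
#'
#' @param structure An `allodeck_structure`.
#' @param cutoff Spring cutoff distance in Angstrom (default 15).
#' @return A list with `correlation` (n x n matrix, dimnames = residue ids),
#'   `nodes` (tibble), and `eigenvalues` of the Hessian.
#' @export
enm_cross_correlation <- function(structure, cutoff = 15) {
  nodes <- residue_nodes(structure)
  n <- nrow(nodes)
  if (n < 3) stop("too few residues for an elastic network", call. = FALSE)
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  hess <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cutoff || d[i, j] < 1e-9) next
      v <- xyz[j, ] - xyz[i, ]
      blk <- -outer(v, v) / sum(v^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      hess[ii, jj] <- blk
      hess[jj, ii] <- blk
      hess[ii, ii] <- hess[ii, ii] - blk
      hess[jj, jj] <- hess[jj, jj] - blk
    }
  }
  eig <- eigen(hess, symmetric = TRUE)
  vals <- eig$values
  tol <- max(vals) * 1e-8
  nonzero <- which(vals > tol)
  if (length(vals) - length(nonzero) < 6) {
    stop("elastic network is singular beyond rigid-body motion; too few contacts",
         call. = FALSE)
  }
  inv_vals <- 1 / vals[nonzero]
  cov <- eig$vectors[, nonzero, drop = FALSE] %*%
    (inv_vals * t(eig$vectors[, nonzero, drop = FALSE]))
  tr <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in i:n) {
      jj <- (3 * j - 2):(3 * j)
      tr[i, j] <- sum(diag(cov[ii, jj, drop = FALSE]))
      tr[j, i] <- tr[i, j]
    }
  }
  corr <- tr / sqrt(outer(diag(tr), diag(tr)))
  dimnames(corr) <- list(nodes$res_id, nodes$res_id)
  list(correlation = corr, nodes = nodes, eigenvalues = vals)
}

#' Motion-correlation z-scores of candidate pockets
#'
#' For each candidate pocket, the raw motion correlation is the mean
#' elastic-network cross-correlation over residue pairs (one in the
#' orthosteric pocket lining, one in the candidate lining). Z-scores are
#' computed across the candidates (population standard deviation). Pass
#' `zmin` to retain only candidates scoring strictly above it (the
#' conventional threshold is 0.5).
#'
#' @param structure An `allodeck_structure`.
#' @param orthosteric A one-row pocket (the declared orthosteric site).
#' @param candidates A pocket tibble with at least two rows.
#' @param cutoff Elastic-network cutoff (Angstrom).
#' @param zmin Optional strict z-score threshold for filtering.
#' @return The candidates with `raw_correlation` and `z_score` columns,
#'   sorted by `z_score` descending (filtered when `zmin` is given).
#' @export
motion_correlation_z <- function(structure, orthosteric, candidates,
                                 cutoff = 15, zmin = NULL) {
  if (nrow(candidates) < 2) {
    stop("z-scoring needs at least two candidate pockets", call. = FALSE)
  }
  enm <- enm_cross_correlation(structure, cutoff = cutoff)
  corr <- enm$correlation
  ortho_res <- intersect(orthosteric$lining[[1]], rownames(corr))
  if (!length(ortho_res)) {
    stop("orthosteric pocket lining shares no residues with the structure",
         call. = FALSE)
  }
  raw <- vapply(seq_len(nrow(candidates)), function(k) {
    cand_res <- intersect(candidates$lining[[k]], rownames(corr))
    if (!length(cand_res)) return(NA_real_)
    mean(corr[ortho_res, cand_res, drop = FALSE])
  }, 0)
  mu <- mean(raw, na.rm = TRUE)
  sig <- sqrt(mean((raw[!is.na(raw)] - mu)^2))
  z <- if (sig > 0) (raw - mu) / sig else rep(0, length(raw))
  out <- candidates
  out$raw_correlation <- raw
  out$z_score <- z
  out <- dplyr::arrange(out, dplyr::desc(.data$z_score))
  if (!is.null(zmin)) out <- out[!is.na(out$z_score) & out$z_score > zmin, ]
  out
}

# -- consensus ----------------------------------------------------------------

#' Consensus allosteric sites across methods and complexes
#'
#' Pools pockets from several (method, complex) site sets, merges them
#' greedily by centroid distance (after a canonical coordinate sort, so the
#' result is independent of input order), and retains a merged site only if
#' it was detected in every complex and by at least `min_methods` distinct
#' methods. The merged centroid is the mean of the member centroids.
#'
#' @param site_sets Either a single pocket tibble carrying `method` and
#'   `complex` columns, or a list of such tibbles (or of
#'   `list(method=, complex=, pockets=)` entries).
#' @param min_methods Minimum number of distinct detection methods.
#' @param merge_distance Centroid distance (Angstrom) below which pockets
#'   are considered the same site.
#' @return A tibble of consensus sites: id, centroid, member count, methods,
#'   complexes and member pocket ids.
#' @export
consensus_sites <- function(site_sets, min_methods = 2L, merge_distance = 4.0) {
  pool <- normalize_site_sets(site_sets)
  complexes <- unique(pool$complex)
  if (length(complexes) < 2) {
    stop("consensus needs pockets from at least two complexes", call. = FALSE)
  }
  if (!nrow(pool)) return(empty_consensus())
  # canonical order makes greedy clustering order-independent
  pool <- pool[order(pool$cx, pool$cy, pool$cz, pool$method,
                     pool$complex, pool$id), ]
  cluster <- integer(nrow(pool))
  centers <- list()
  members <- list()
  for (i in seq_len(nrow(pool))) {
    p <- c(pool$cx[i], pool$cy[i], pool$cz[i])
    hit <- 0L
    for (cl in seq_along(centers)) {
      if (sqrt(sum((centers[[cl]] - p)^2)) <= merge_distance) { hit <- cl; break }
    }
    if (hit == 0L) {
      centers[[length(centers) + 1L]] <- p
      members[[length(members) + 1L]] <- i
      cluster[i] <- length(centers)
    } else {
      members[[hit]] <- c(members[[hit]], i)
      centers[[hit]] <- colMeans(pocket_centroids(pool[members[[hit]], ]))
      cluster[i] <- hit
    }
  }
  rows <- list()
  for (cl in seq_along(members)) {
    m <- pool[members[[cl]], ]
    meths <- unique(m$method)
    comps <- unique(m$complex)
    if (length(meths) < min_methods) next
    if (!all(complexes %in% comps)) next
    cen <- colMeans(pocket_centroids(m))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("S%02d", length(rows) + 1L),
      cx = cen[1], cy = cen[2], cz = cen[3],
      n_members = nrow(m),
      methods = list(sort(meths)), complexes = list(sort(comps)),
      member_ids = list(paste(m$method, m$complex, m$id, sep = "/")),
      lining = list(sort(unique(unlist(m$lining)))))
  }
  if (!length(rows)) return(empty_consensus())
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$cx, out$cy, out$cz), ]
  out$id <- sprintf("S%02d", seq_len(nrow(out)))
  out
}

empty_consensus <- function() {
  tibble::tibble(id = character(0), cx = numeric(0), cy = numeric(0),
                 cz = numeric(0), n_members = integer(0), methods = list(),
                 complexes = list(), member_ids = list(), lining = list())
}

normalize_site_sets <- function(site_sets) {
  if (is.data.frame(site_sets)) return(site_sets)
  parts <- lapply(site_sets, function(s) {
    if (is.data.frame(s)) return(s)
    p <- s$pockets
    p$method <- s$method
    p$complex <- s$complex
    p
  })
  dplyr::bind_rows(parts)
}

#' Read / write pockets as JSON
#'
#' @param pockets A pocket tibble.
#' @param path JSON path.
#' @return `path` invisibly for the writer; a pocket tibble for the reader.
#' @export
write_pockets_json <- function(pockets, path) {
  recs <- lapply(seq_len(nrow(pockets)), function(i) {
    list(id = pockets$id[i],
         centroid = c(pockets$cx[i], pockets$cy[i], pockets$cz[i]),
         volume = pockets$volume[i],
         ligandability = pockets$ligandability[i],
         z_score = pockets$z_score[i],
         lining_residues = pockets$lining[[i]],
         method = pockets$method[i], complex = pockets$complex[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_pockets_json
#' @export
read_pockets_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    pocket(id = r$id, centroid = unlist(r$centroid),
           lining_residues = as.character(unlist(r$lining_residues)),
           volume = r$volume %||% NA_real_,
           ligandability_score = r$ligandability %||% NA_real_,
           z_score = r$z_score %||% NA_real_,
           method = r$method %||% NA_character_,
           complex = r$complex %||% NA_character_)
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
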