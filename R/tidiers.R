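# broom-style tidiers and ggplot2 autoplot methods

#' Tidy a residue energy profile
#'
#' @param x An `allodeck_profile`.
#' @param ... Unused.
#' @return The per-residue tibble of the nine binding-recognition vectors.
#' @export
tidy.allodeck_profile <- function(x, ...) x$residues

#' One-row summary of a residue energy profile
#'
#' @param x An `allodeck_profile`.
#' @param ... Unused.
#' @return Tibble with the intermolecular score, normalized affinity,
#'   rotatable-bond count and number of contributing residues.
#' @export
glance.allodeck_profile <- function(x, ...) {
  tibble::tibble(intermolecular_score = x$intermolecular_score,
                 normalized_affinity = x$normalized_affinity,
                 n_rotatable = x$n_rotatable,
                 n_contributing = sum(x$residues$residue_energy != 0))
}

#' Tidy a docked pose list
#'
#' @param x An `allodeck_poses` list.
#' @param ... Unused.
#' @return Tibble with pose rank, score, and heavy-atom RMSD to the best
#'   pose.
#' @export
tidy.allodeck_poses <- function(x, ...) {
  tibble::tibble(
    pose = seq_along(x),
    score = vapply(x, `[[`, 0, "score"),
    rmsd_to_best = vapply(x, function(p) pose_rmsd(p, x[[1]]), 0))
}

#' Tidy a modulator verdict
#'
#' @param x An `allodeck_verdict`.
#' @param ... Unused.
#' @return One-row tibble with site, effective/control energies, delta and
#'   verdict.
#' @export
tidy.allodeck_verdict <- function(x, ...) {
  tibble::tibble(site = x$site, verdict = x$verdict,
                 effective = x$effective, dg_control = x$dg_control,
                 delta = x$delta, adjacency = x$adjacency,
                 tolerance = x$tolerance)
}

#' @export
glance.allodeck_verdict <- function(x, ...) tidy(x)

#' Plot the top residue contributions of a profile
#'
#' Stacked per-residue bars of the weighted residue energy split into its
#' steric and non-steric parts (unweighted term shares scaled to the
#' weighted total), most favorable residues first.
#'
#' @param object An `allodeck_profile`.
#' @param k Number of residues to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allodeck_profile <- function(object, k = 10, ...) {
  top <- rank_residues(object, min(k, nrow(object$residues)))
  long <- tidyr::pivot_longer(
    top[, c("res_id", "steric", "hbond", "hydrophobic")],
    cols = c("steric", "hbond", "hydrophobic"),
    names_to = "term", values_to = "value")
  long$res_id <- factor(long$res_id, levels = rev(top$res_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$res_id, y = .data$value,
                                     fill = .data$term)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "term value (unweighted)",
                  title = "Top residue contributions") +
    ggplot2::theme_minimal()
}

#' Plot docked pose scores
#'
#' @param object An `allodeck_poses` list.
#' @param ... Unused.
#' @return A ggplot object: score against pose rank.
#' @export
autoplot.allodeck_poses <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pose, y = .data$score)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "pose rank", y = "score (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy component table
#'
#' Side-by-side component bars per site with the reconstructed total
#' overlaid as points.
#'
#' @param tbl A component table ([load_energy_table()] output).
#' @return A ggplot object.
#' @export
plot_energy_components <- function(tbl) {
  tbl <- reconstruct_totals(tbl)
  comp <- intersect(COMPONENT_COLS, names(tbl))
  long <- tidyr::pivot_longer(tbl[, c("site", comp)], cols = -"site",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = tbl,
                        ggplot2::aes(x = .data$site, y = .data$G_calc),
                        inherit.aes = FALSE, shape = 18, size = 3) +
    ggplot2::labs(x = "site", y = "kcal/mol") +
    ggplot2::theme_minimal()
}
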