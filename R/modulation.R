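# MM-PBSA-WSAS component bookkeeping: reconstruct totals from component
# tables, rank candidate sites, and classify an allosteric modulator as
# PAM / NAM / silent.

COMPONENT_COLS <- c("E_VDW", "E_eel", "E_int", "G_pol", "G_nonpol", "TS")

parse_pm_cell <- function(s, row, col) {
  s <- gsub("−", "-", trimws(s))          # normalize U+2212 minus
  if (s %in% c("", "NA", "N/A", "NA *", "N/A *")) {
    return(c(value = NA_real_, unc = NA_real_))
  }
  parts <- strsplit(s, "±|\\+/-")[[1]]
  v <- suppressWarnings(as.numeric(trimws(parts[1])))
  if (is.na(v)) {
    stop(sprintf("unparseable numeric cell '%s' (row %d, column %s)",
                 s, row, col), call. = FALSE)
  }
  u <- if (length(parts) > 1) {
    suppressWarnings(as.numeric(trimws(parts[2])))
  } else NA_real_
  c(value = v, unc = u)
}

#' Load a free-energy component table
#'
#' Reads a TSV whose header names recognized component columns (`E_VDW`,
#' `E_eel`, `E_int`, `G_pol`, `G_nonpol`, `TS`, `G_total`); cells may carry
#' "value ± uncertainty" and minus signs may be ASCII or U+2212.
#'
#' @param path TSV path.
#' @return A tibble with one row per site: `site`, component columns, and
#'   matching `*_unc` uncertainty columns.
#' @export
load_energy_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!nrow(raw)) {
    return(tibble::tibble(site = character(0)))
  }
  site_col <- if ("site" %in% names(raw)) "site" else names(raw)[1]
  out <- tibble::tibble(site = trimws(raw[[site_col]]))
  for (col in setdiff(names(raw), site_col)) {
    vals <- t(vapply(seq_len(nrow(raw)),
                     function(i) parse_pm_cell(raw[[col]][i], i, col),
                     c(value = 0, unc = 0)))
    out[[col]] <- unname(vals[, "value"])
    out[[paste0(col, "_unc")]] <- unname(vals[, "unc"])
  }
  out
}

#' MM-PBSA-WSAS total from components
#'
#' Returns `E_VDW + E_eel + E_int + G_pol + G_nonpol - TS`; `E_int` is
#' required only when present in the record (complex tables carry it,
#' binding tables do not).
#'
#' @param rec A one-row data frame or named list with the component fields.
#' @return The total in kcal/mol.
#' @export
total_from_components <- function(rec) {
  get1 <- function(nm, required = TRUE) {
    v <- rec[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      if (required) stop("missing component '", nm, "'", call. = FALSE)
      return(0)
    }
    as.numeric(v)
  }
  get1("E_VDW") + get1("E_eel") + get1("E_int", required = FALSE) +
    get1("G_pol") + get1("G_nonpol") - get1("TS")
}

#' Reconstruct totals for every row of a component table
#'
#' Adds `G_calc` (the component sum) and `G_calc_unc` (uncertainties
#' combined in quadrature; informational only) and, when the table prints a
#' total, `G_resid = G_calc - G_total`.
#'
#' @param tbl A tibble from [load_energy_table()].
#' @return The table with reconstruction columns appended.
#' @export
reconstruct_totals <- function(tbl) {
  tbl$G_calc <- vapply(seq_len(nrow(tbl)),
                       function(i) total_from_components(tbl[i, ]), 0)
  unc_cols <- intersect(paste0(COMPONENT_COLS, "_unc"), names(tbl))
  if (length(unc_cols)) {
    u2 <- rowSums(as.matrix(tbl[, unc_cols])^2, na.rm = TRUE)
    tbl$G_calc_unc <- sqrt(u2)
  }
  if ("G_total" %in% names(tbl)) tbl$G_resid <- tbl$G_calc - tbl$G_total
  tbl
}

#' Rank sites by free-energy total
#'
#' @param records A component table ([load_energy_table()] output or any
#'   data frame with the component columns and a `site` column).
#' @return The table sorted ascending by the reconstructed total (most
#'   favorable first); ties keep input order.
#' @export
rank_sites <- function(records) {
  if (!nrow(records)) stop("no records to rank", call. = FALSE)
  records <- reconstruct_totals(records)
  records[order(records$G_calc, seq_len(nrow(records))), ]
}

#' Rank sites within one row of a docking-score table
#'
#' The docking-score table is wide (one row per modulator, one column per
#' site); this extracts a modulator's row, drops unavailable sites and sorts
#' ascending (most favorable score first).
#'
#' @param tbl Wide score table with the modulator labels in column `site`
#'   (as loaded by [load_energy_table()]).
#' @param am Modulator row label, e.g. `"C-2"`.
#' @return A tibble with `site` and `score` sorted ascending.
#' @export
rank_docking_scores <- function(tbl, am) {
  i <- which(tbl$site == am)
  if (!length(i)) stop("no row labeled '", am, "'", call. = FALSE)
  cols <- setdiff(names(tbl), c("site", grep("_unc$", names(tbl), value = TRUE)))
  score <- vapply(cols, function(cl) as.numeric(tbl[[cl]][i[1]]), 0)
  out <- tibble::tibble(site = cols, score = unname(score))
  out <- out[!is.na(out$score), ]
  out[order(out$score, seq_len(nrow(out))), ]
}

#' Classify an allosteric modulator as PAM, NAM or silent
#'
#' Compares the orthosteric ligand's binding free energy with the modulator
#' present against the no-modulator control. When the modulator pocket is
#' adjacent to the orthosteric site, the modulator is treated as part of the
#' receptor and `dg_am_as_receptor` is the effective value (the H*
#' convention); otherwise `dg_with_am` is used. The verdict is PAM when the
#' effective value is below `dg_control - tolerance`, NAM when above
#' `dg_control + tolerance`, else silent.
#'
#' @param dg_control Binding free energy without the modulator (kcal/mol).
#' @param dg_with_am Binding free energy with the modulator bound.
#' @param dg_am_as_receptor Binding free energy with the modulator folded
#'   into the receptor; required when `adjacency` is `TRUE`.
#' @param adjacency Is the modulator pocket adjacent to the orthosteric
#'   site? (User-declared.)
#' @param tolerance Dead-zone half-width in kcal/mol (default 0).
#' @param site Optional site label carried into the result.
#' @return An `allodeck_verdict`: site, effective and control energies,
#'   the difference, and the verdict string.
#' @export
classify_modulator <- function(dg_control, dg_with_am,
                               dg_am_as_receptor = NULL, adjacency = FALSE,
                               tolerance = 0, site = NA_character_) {
  stopifnot(is.numeric(dg_control), is.numeric(dg_with_am))
  if (adjacency && (is.null(dg_am_as_receptor) || is.na(dg_am_as_receptor))) {
    stop("adjacency requires dg_am_as_receptor (the modulator-as-receptor value)",
         call. = FALSE)
  }
  effective <- if (adjacency) dg_am_as_receptor else dg_with_am
  verdict <- if (effective < dg_control - tolerance) "PAM"
  else if (effective > dg_control + tolerance) "NAM"
  else "silent"
  structure(list(site = site, effective = effective,
                 dg_control = dg_control, dg_with_am = dg_with_am,
                 dg_am_as_receptor = if (is.null(dg_am_as_receptor))
                   NA_real_ else dg_am_as_receptor,
                 adjacency = adjacency, tolerance = tolerance,
                 delta = effective - dg_control, verdict = verdict),
            class = "allodeck_verdict")
}

#' @export
print.allodeck_verdict <- function(x, ...) {
  cat(sprintf(
    "<allodeck_verdict> %s: %s (effective %.2f vs control %.2f kcal/mol, delta %+.2f)\n",
    ifelse(is.na(x$site), "site", x$site), x$verdict, x$effective,
    x$dg_control, x$delta))
  invisible(x)
}

#' Modulator verdict straight from a binding table
#'
#' Convenience wrapper: picks the control row, the site row and (optionally)
#' the modulator-as-receptor row out of a component table, reconstructs
#' their totals and calls [classify_modulator()].
#'
#' @param tbl A component table with a `site` column.
#' @param site Site label of the modulator pocket.
#' @param control Label of the no-modulator control row.
#' @param am_as_receptor Label of the modulator-as-receptor row (e.g.
#'   `"H*"`), required when `adjacency` is `TRUE`.
#' @param adjacency Is the pocket adjacent to the orthosteric site?
#' @param tolerance Dead-zone half-width (kcal/mol).
#' @return An `allodeck_verdict`.
#' @export
classify_from_table <- function(tbl, site, control = "No Ligand",
                                am_as_receptor = NULL, adjacency = FALSE,
                                tolerance = 0) {
  tbl <- reconstruct_totals(tbl)
  row_of <- function(lab) {
    i <- which(tbl$site == lab)
    if (!length(i)) stop("no row labeled '", lab, "' in table", call. = FALSE)
    tbl$G_calc[i[1]]
  }
  classify_modulator(
    dg_control = row_of(control),
    dg_with_am = row_of(site),
    dg_am_as_receptor = if (!is.null(am_as_receptor)) row_of(am_as_receptor),
    adjacency = adjacency, tolerance = tolerance, site = site)
}
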