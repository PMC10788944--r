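# The degrader TC score: sum of per-interaction energies of the two
# protein-binding moieties (warhead and L^E3) within the refined ternary
# complex.  Linker-mediated interactions are deliberately excluded; the more
# negative the score, the more stable the predicted complex.  Absolute
# values are engine-dependent: orderings within a degrader series are the
# deliverable.

#' Degrader ternary-complex score
#'
#' `e_warhead` sums the energies of every interaction the warhead
#' establishes with the proteins; `e_le3` does the same for the E3 ligand;
#' `total = e_warhead + e_le3` exactly. Linker contacts are excluded. By
#' default each moiety is scored against both proteins (warhead contacts
#' with the E3 ligase count); set `cognate_only = TRUE` to restrict each
#' moiety to its own receptor.
#'
#' @param tc a refined `ternary_complex`.
#' @param cognate_only logical; restrict warhead to POI and L^E3 to E3L.
#' @return a `degrader_score`: list with `e_warhead`, `e_le3`, `total`
#'   (kcal/mol) and the two interaction tables.
#' @export
degrader_score <- function(tc, cognate_only = FALSE) {
  stopifnot(inherits(tc, "ternary_complex"))
  if (!length(tc$warhead_atoms) || !length(tc$le3_atoms)) {
    stop("both moiety atom lists (warhead, L^E3) must be non-empty")
  }
  both <- sort(c(tc$poi_atoms, tc$e3l_atoms))
  rec_w <- if (cognate_only) tc$poi_atoms else both
  rec_e <- if (cognate_only) tc$e3l_atoms else both
  iw <- enumerate_interactions(tc, tc$warhead_atoms, rec_w,
                               warn_unrefined = FALSE)
  ie <- enumerate_interactions(tc, tc$le3_atoms, rec_e,
                               warn_unrefined = FALSE)
  ew <- .sum_interaction_energies(iw, tc)
  ee <- .sum_interaction_energies(ie, tc)
  structure(list(e_warhead = ew, e_le3 = ee, total = ew + ee,
                 warhead_interactions = iw, le3_interactions = ie,
                 cognate_only = cognate_only),
            class = "degrader_score")
}

#' @export
print.degrader_score <- function(x, ...) {
  cat(sprintf("<degrader_score> total %.2f kcal/mol (warhead %.2f + L^E3 %.2f)\n",
              x$total, x$e_warhead, x$e_le3))
  cat(sprintf("  %d warhead and %d L^E3 interactions\n",
              nrow(x$warhead_interactions), nrow(x$le3_interactions)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a degrader score into its per-interaction table
#'
#' @param x a `degrader_score`.
#' @param ... unused.
#' @return tibble with one row per interaction: `moiety`, `kind`,
#'   `ligand_atom`, `protein_atom`, `distance`.
#' @method tidy degrader_score
#' @export
tidy.degrader_score <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$warhead_interactions), moiety = "warhead"),
    dplyr::mutate(tibble::as_tibble(x$le3_interactions), moiety = "le3")
  ) |>
    dplyr::relocate("moiety")
}

#' One-row summary of a degrader score
#'
#' @param x a `degrader_score`.
#' @param ... unused.
#' @return one-row tibble: `e_warhead`, `e_le3`, `total`, `n_interactions`.
#' @method glance degrader_score
#' @export
glance.degrader_score <- function(x, ...) {
  tibble::tibble(e_warhead = x$e_warhead, e_le3 = x$e_le3, total = x$total,
                 n_interactions = nrow(x$warhead_interactions) +
                   nrow(x$le3_interactions))
}

#' Label a degrader by measured degradation
#'
#' Convention used in report annotations: more than 50 percent degradation
#' is a strong degrader.
#'
#' @param percent_degradation numeric vector (0-100).
#' @return character vector `"strong"`/`"poor"`.
#' @export
degradation_label <- function(percent_degradation) {
  ifelse(percent_degradation > 50, "strong", "poor")
}

#' Protein-protein interface summary
#'
#' Enumerates POI vs E3-ligase interactions (all PROTAC atoms excluded),
#' counts them by kind, lists the interface residues of each protein, and
#' measures the contact surface as the buried solvent-accessible surface
#' area: `(SASA(POI) + SASA(E3L) - SASA(both)) / 2`.
#'
#' @param tc a `ternary_complex`.
#' @return a `ppi_summary`: list with `hbonds`, `salt_bridges`,
#'   `nonbonded_contacts`, `interface_residues` (tibble `protein`, `chain`,
#'   `residue_number`), `contact_area` (Angstrom^2) and the raw interaction
#'   table.
#' @export
ppi_summary <- function(tc) {
  stopifnot(inherits(tc, "ternary_complex"))
  if (!length(tc$poi_atoms) || !length(tc$e3l_atoms)) {
    stop("both protein atom lists must be non-empty")
  }
  inters <- enumerate_interactions(tc, tc$poi_atoms, tc$e3l_atoms,
                                   warn_unrefined = FALSE)
  m <- tc$structure
  res_of <- function(idx) {
    if (!length(idx)) {
      return(tibble::tibble(chain = character(), residue_number = integer()))
    }
    dplyr::distinct(tibble::tibble(chain = m$atoms$chain_id[idx],
                                   residue_number = m$atoms$residue_number[idx]))
  }
  iface <- dplyr::bind_rows(
    dplyr::mutate(res_of(unique(inters$ligand_atom)), protein = "POI"),
    dplyr::mutate(res_of(unique(inters$protein_atom)), protein = "E3L"))
  sasa_poi <- sasa(subset_structure(m, tc$poi_atoms))
  sasa_e3 <- sasa(subset_structure(m, tc$e3l_atoms))
  sasa_both <- sasa(subset_structure(m, sort(c(tc$poi_atoms, tc$e3l_atoms))))
  area <- max(0, (sum(sasa_poi) + sum(sasa_e3) - sum(sasa_both)) / 2)
  structure(list(
    hbonds = sum(inters$kind == "HBOND"),
    salt_bridges = sum(inters$kind == "SALT_BRIDGE"),
    nonbonded_contacts = sum(inters$kind == "NONBONDED"),
    interface_residues = dplyr::relocate(iface, "protein"),
    contact_area = area,
    interactions = inters
  ), class = "ppi_summary")
}

#' @export
print.ppi_summary <- function(x, ...) {
  cat(sprintf("<ppi_summary> H-bonds %d | salt bridges %d | nonbonded %d | contact area %.1f A^2\n",
              x$hbonds, x$salt_bridges, x$nonbonded_contacts, x$contact_area))
  invisible(x)
}

#' @rdname ppi_summary
#' @param x a `ppi_summary`.
#' @param ... unused.
#' @method glance ppi_summary
#' @export
glance.ppi_summary <- function(x, ...) {
  tibble::tibble(hbonds = x$hbonds, salt_bridges = x$salt_bridges,
                 nonbonded_contacts = x$nonbonded_contacts,
                 n_interface_residues = nrow(x$interface_residues),
                 contact_area = x$contact_area)
}
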