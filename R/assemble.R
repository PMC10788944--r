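# Half-complex minimization and the linker-superposition merge that produces
# the ternary complex: the reciprocal orientation of the two proteins is
# obtained purely from superposing the two copies of the linker.

#' Minimize a half-complex with the linker free
#'
#' Linker atoms and all hydrogens are free; protein and moiety heavy atoms
#' are positionally restrained (harmonic, `config$restraint_k`, default 100
#' kcal/mol/Angstrom^2) so the binding poses are respected while the linker
#' relaxes into a clash-free, solvent-facing orientation.
#'
#' @param half a `half_complex`.
#' @param config a [min_config()].
#' @return the minimized `half_complex`; attributes `e_start`, `e_end`
#'   (kcal/mol) and `max_restrained_moved` (Angstrom).
#' @export
minimize_half <- function(half, config = min_config()) {
  stopifnot(inherits(half, "half_complex"))
  m <- half$structure
  hyd <- which(!is_heavy(m))
  mobile <- sort(unique(c(half$linker_atoms, hyd)))
  restrained <- setdiff(seq_len(n_atoms(m)), mobile)
  res <- minimize_structure(m, mobile = mobile, restrained = restrained,
                            config = config)
  moved <- sqrt(rowSums((coords(res$structure)[restrained, , drop = FALSE] -
                           coords(m)[restrained, , drop = FALSE])^2))
  if (length(moved) && max(moved) > 0.3) {
    warning("restrained heavy atoms moved up to ",
            sprintf("%.2f", max(moved)), " A (> 0.3 A)")
  }
  out <- half
  out$structure <- res$structure
  attr(out, "e_start") <- res$e_start
  attr(out, "e_end") <- res$e_end
  attr(out, "max_restrained_moved") <- if (length(moved)) max(moved) else 0
  out
}

#' Construct a ternary-complex model object
#'
#' @param structure a tagged `mol_structure`.
#' @param assembly_rmsd linker-superposition fit RMSD (Angstrom).
#' @param refined logical.
#' @param mapping_note free text about the linker-mapping choice.
#' @return a `ternary_complex`: list with `structure`, the five index lists
#'   (`poi_atoms`, `e3l_atoms`, `warhead_atoms`, `linker_atoms`,
#'   `le3_atoms`), `assembly_rmsd`, `refined`.
#' @export
new_ternary_complex <- function(structure, assembly_rmsd = NA_real_,
                                refined = FALSE, mapping_note = "") {
  tags <- structure$atoms$origin_tag
  obj <- list(structure = structure,
              poi_atoms = which(tags == "POI"),
              e3l_atoms = which(tags == "E3L"),
              warhead_atoms = which(tags == "WARHEAD"),
              linker_atoms = which(tags == "LINKER"),
              le3_atoms = which(tags == "LE3"),
              assembly_rmsd = assembly_rmsd,
              refined = refined,
              mapping_note = mapping_note)
  n <- n_atoms(structure)
  if (length(c(obj$poi_atoms, obj$e3l_atoms, obj$warhead_atoms,
               obj$linker_atoms, obj$le3_atoms)) != n) {
    stop("origin tags must partition the ternary-complex atoms")
  }
  class(obj) <- "ternary_complex"
  obj
}

#' @export
print.ternary_complex <- function(x, ...) {
  cat("<ternary_complex>", x$structure$title, "\n")
  cat(sprintf("  POI %d | E3L %d | warhead %d | linker %d | L^E3 %d atoms\n",
              length(x$poi_atoms), length(x$e3l_atoms),
              length(x$warhead_atoms), length(x$linker_atoms),
              length(x$le3_atoms)))
  cat(sprintf("  assembly_rmsd = %.4f A | refined = %s\n",
              x$assembly_rmsd, x$refined))
  invisible(x)
}

# PROTAC atom indices of a ternary complex
protac_atoms <- function(tc) {
  sort(c(tc$warhead_atoms, tc$linker_atoms, tc$le3_atoms))
}

#' Merge two half-complexes by superposing their linkers
#'
#' The linker copies of the two halves must be chemically identical
#' (graph-isomorphic). Their atom correspondence is found by isomorphism
#' anchored at the junction atoms; for symmetric linkers every anchored
#' mapping is tried and the one with the lowest superposition RMSD is kept
#' (ties broken canonically and noted). The whole E3-side half is then moved
#' by the Kabsch fit of its linker heavy atoms onto the POI-side linker, the
#' E3-side linker copy is deleted, and the L^E3-linker junction bond is
#' formed to the surviving POI-side linker. POI-side coordinates are
#' untouched.
#'
#' @param poi_half,e3_half `half_complex` objects with identical linkers.
#' @return a `ternary_complex`; `assembly_rmsd` is the linker-fit RMSD.
#' @export
superpose_and_merge <- function(poi_half, e3_half) {
  stopifnot(inherits(poi_half, "half_complex"),
            inherits(e3_half, "half_complex"))
  lp <- subset_structure(poi_half$structure, poi_half$linker_atoms)
  le <- subset_structure(e3_half$structure, e3_half$linker_atoms)
  maps <- mol_isomorphisms(le, lp, heavy_only = FALSE)
  if (!length(maps)) {
    stop("the two half-complexes do not carry chemically identical linkers")
  }
  # local indices of the anchors inside the linker subsets; the local
  # junction is derivable from the bond table when not recorded
  derive_local <- function(half) {
    b <- half$structure$bonds
    k <- b$i %in% half$linker_atoms & b$j %in% half$moiety_atoms |
      b$j %in% half$linker_atoms & b$i %in% half$moiety_atoms
    at <- intersect(c(b$i[k], b$j[k]), half$linker_atoms)
    if (length(at) != 1) stop("linker must bond the moiety at exactly one atom")
    at
  }
  if (is.na(e3_half$linker_junction_local)) {
    e3_half$linker_junction_local <- derive_local(e3_half)
  }
  if (is.na(poi_half$linker_junction_local)) {
    poi_half$linker_junction_local <- derive_local(poi_half)
  }
  e3_local <- match(e3_half$linker_junction_local, e3_half$linker_atoms)
  e3_distal <- match(e3_half$linker_junction_distal, e3_half$linker_atoms)
  poi_local <- match(poi_half$linker_junction_local, poi_half$linker_atoms)
  poi_distal <- match(poi_half$linker_junction_distal, poi_half$linker_atoms)
  ok_anchor <- function(mp) {
    (is.na(e3_local) || is.na(poi_distal) || mp[[e3_local]] == poi_distal) &&
      (is.na(e3_distal) || is.na(poi_local) || mp[[e3_distal]] == poi_local)
  }
  maps <- Filter(ok_anchor, maps)
  if (!length(maps)) {
    stop("no linker isomorphism respects the junction anchors; ",
         "check the junction bookkeeping of the two halves")
  }
  hv <- which(is_heavy(le))
  fits <- lapply(maps, function(mp) {
    kabsch_fit(coords(le)[hv, , drop = FALSE],
               coords(lp)[mp[hv], , drop = FALSE])
  })
  rmsds <- vapply(fits, `[[`, numeric(1), "fit_rmsd")
  best <- which(rmsds <= min(rmsds) + 1e-9)
  note <- ""
  if (length(maps) > 1) {
    note <- sprintf("symmetric linker: %d anchored mapping(s), rmsd range %.4f-%.4f A; minimum kept",
                    length(maps), min(rmsds), max(rmsds))
    message(note)
  }
  if (length(best) > 1) {      # exact tie: canonical (lexicographic) order
    keys <- vapply(maps[best], function(mp) paste(mp, collapse = ","), "")
    best <- best[order(keys)]
  }
  choice <- best[1]
  tf <- fits[[choice]]
  mp_choice <- maps[[choice]]

  e3_moved <- e3_half$structure
  coords(e3_moved) <- apply_transform(coords(e3_moved), tf)
  # drop the E3-side linker copy ("excess atoms removed")
  keep_e3 <- sort(c(e3_half$protein_atoms, e3_half$moiety_atoms))
  e3_trim <- subset_structure(e3_moved, keep_e3)

  # LE3 atom bonded to the E3-side linker local junction -> bonds to the
  # POI-side linker atom the chosen mapping puts underneath it
  adj_e3 <- .adjacency(e3_half$structure)
  le3_anchor_old <- intersect(adj_e3[[e3_half$linker_junction_local]],
                              e3_half$moiety_atoms)
  if (length(le3_anchor_old) != 1) {
    stop("E3-side linker junction must bond exactly one moiety atom")
  }
  le3_anchor_new <- match(le3_anchor_old, keep_e3)
  bond_target <- poi_half$linker_atoms[mp_choice[[e3_local]]]
  if (!is.na(poi_half$linker_junction_distal) &&
      bond_target != poi_half$linker_junction_distal) {
    stop("chosen linker mapping contradicts the recorded distal junction")
  }

  merged <- combine_structures(poi_half$structure, e3_trim,
                               title = "ternary complex model")
  np <- n_atoms(poi_half$structure)
  merged <- add_bond(merged, bond_target, np + le3_anchor_new)
  new_ternary_complex(merged, assembly_rmsd = tf$fit_rmsd,
                      refined = FALSE, mapping_note = note)
}
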