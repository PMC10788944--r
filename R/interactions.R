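# Typed protein-ligand / protein-protein interaction enumeration
# (LigPlot-style: hydrogen bonds, salt bridges, nonbonded contacts) and the
# per-interaction energy model behind the degrader score.

.hbond_dist <- 3.5     # donor-acceptor heavy-atom cutoff, Angstrom
.hbond_angle <- 120    # minimum D-H...A angle, degrees
.salt_dist <- 4.0      # charged N/O pair cutoff, Angstrom
.contact_dist <- 4.0   # nonbonded heavy-atom contact cutoff, Angstrom

.polar_elements <- c("N", "O")

#' Enumerate typed interactions between two atom groups
#'
#' Classifies every heavy-atom pair (one atom from each group) within the
#' contact cutoff. A pair is a SALT_BRIDGE when two oppositely formally
#' charged N/O atoms are within 4.0 Angstrom; an HBOND when an N/O donor
#' carrying a hydrogen is within 3.5 Angstrom of an N/O acceptor with a
#' D-H...A angle of at least 120 degrees; otherwise a NONBONDED contact
#' (<= 4.0 Angstrom). Each pair is reported once with its highest-priority
#' kind (SALT_BRIDGE > HBOND > NONBONDED).
#'
#' @param tc a `ternary_complex` (or any `mol_structure`).
#' @param ligand_atoms,receptor_atoms disjoint 1-based atom index vectors.
#' @param warn_unrefined warn when `tc` is a ternary complex that has not
#'   been refined.
#' @return tibble with columns `kind`, `ligand_atom`, `protein_atom`,
#'   `distance` (Angstrom); class `tc_interactions`.
#' @export
enumerate_interactions <- function(tc, ligand_atoms, receptor_atoms,
                                   warn_unrefined = TRUE) {
  if (inherits(tc, "ternary_complex") && warn_unrefined && !tc$refined) {
    warning("ternary complex is not refined; interactions may include ",
            "unresolved contacts")
  }
  m <- as_mol_structure(tc)
  ligand_atoms <- as.integer(ligand_atoms)
  receptor_atoms <- as.integer(receptor_atoms)
  if (length(intersect(ligand_atoms, receptor_atoms))) {
    stop("ligand and receptor atom sets overlap")
  }
  empty <- tibble::tibble(kind = character(), ligand_atom = integer(),
                          protein_atom = integer(), distance = numeric())
  xyz <- coords(m)
  el <- m$atoms$element
  fc <- m$atoms$formal_charge
  adj <- .adjacency(m)
  has_h <- vapply(adj, function(nb) any(el[nb] == "H"), logical(1))

  lig <- ligand_atoms[el[ligand_atoms] != "H"]
  rec <- receptor_atoms[el[receptor_atoms] != "H"]
  if (!length(lig) || !length(rec)) return(.as_interactions(empty))
  # candidate pairs within the largest cutoff
  grid <- close_pairs(xyz[c(lig, rec), , drop = FALSE], .contact_dist)
  if (!nrow(grid)) return(.as_interactions(empty))
  glob <- c(lig, rec)
  gi <- glob[grid[, 1]]; gj <- glob[grid[, 2]]
  cross <- (gi %in% lig) != (gj %in% lig)
  gi <- gi[cross]; gj <- gj[cross]
  if (!length(gi)) return(.as_interactions(empty))
  la <- ifelse(gi %in% lig, gi, gj)
  pa <- ifelse(gi %in% lig, gj, gi)
  d <- sqrt(rowSums((xyz[la, , drop = FALSE] - xyz[pa, , drop = FALSE])^2))

  polar <- function(a) el[a] %in% .polar_elements
  is_salt <- polar(la) & polar(pa) & (fc[la] * fc[pa] < 0) & d <= .salt_dist

  hb_geom <- function(don, acc) {
    # TRUE when some H on `don` satisfies the D-H...A angle criterion
    vapply(seq_along(don), function(k) {
      hs <- adj[[don[k]]][el[adj[[don[k]]]] == "H"]
      if (!length(hs)) return(FALSE)
      any(vapply(hs, function(h) {
        v1 <- xyz[don[k], ] - xyz[h, ]
        v2 <- xyz[acc[k], ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= .hbond_angle
      }, logical(1)))
    }, logical(1))
  }
  cand_hb <- polar(la) & polar(pa) & d <= .hbond_dist & !is_salt
  is_hb <- logical(length(d))
  if (any(cand_hb)) {
    k <- which(cand_hb)
    don_lig <- has_h[la[k]] & hb_geom(la[k], pa[k])
    don_rec <- has_h[pa[k]] & hb_geom(pa[k], la[k])
    is_hb[k] <- don_lig | don_rec
  }
  kind <- ifelse(is_salt, "SALT_BRIDGE", ifelse(is_hb, "HBOND", "NONBONDED"))
  out <- tibble::tibble(kind = kind, ligand_atom = la, protein_atom = pa,
                        distance = d)
  .as_interactions(dplyr::arrange(out, .data$distance))
}

.as_interactions <- function(x) {
  class(x) <- c("tc_interactions", class(x))
  x
}

#' Energy of one enumerated interaction
#'
#' Pairwise nonbonded energy (Lennard-Jones + Coulomb with
#' distance-dependent dielectric eps = 4r) of the interacting atom pair;
#' for hydrogen bonds and salt bridges the hydrogens bonded to the two polar
#' atoms are included in the sum, so the electrostatics of the polar groups
#' are captured. Same engine and parameters as the minimizer; negative is
#' favourable.
#'
#' @param inter one row of an [enumerate_interactions()] table (list or
#'   single-row data frame with `kind`, `ligand_atom`, `protein_atom`).
#' @param tc the `ternary_complex` (or `mol_structure`) the indices refer to.
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(inter, tc) {
  m <- as_mol_structure(tc)
  i <- as.integer(inter$ligand_atom); j <- as.integer(inter$protein_atom)
  el <- m$atoms$element
  if (!all(is_valid_element(el[c(i, j)]))) {
    stop("missing force-field parameters for atom ", c(i, j)[1])
  }
  group <- function(a) {
    if (inter$kind %in% c("HBOND", "SALT_BRIDGE")) {
      hs <- .adjacency(m)[[a]]
      c(a, hs[el[hs] == "H"])
    } else a
  }
  gi <- group(i); gj <- group(j)
  xyz <- coords(m)
  q <- m$atoms$partial_charge
  rv <- .atom_rvdw(m); ep <- element_param(el, "lj_eps")
  e <- 0
  for (a in gi) for (b in gj) {
    d <- max(sqrt(sum((xyz[a, ] - xyz[b, ])^2)), 0.05)
    sr6 <- ((rv[a] + rv[b]) / d)^6
    e <- e + sqrt(ep[a] * ep[b]) * (sr6^2 - 2 * sr6) +
      .coulomb_k * q[a] * q[b] / (4 * d^2)
  }
  e
}

# sum of interaction energies for a whole enumeration table
.sum_interaction_energies <- function(inters, tc) {
  if (!nrow(inters)) return(0)
  sum(vapply(seq_len(nrow(inters)), function(k)
    interaction_energy(inters[k, ], tc), numeric(1)))
}
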