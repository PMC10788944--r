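# Molecular structure container shared by proteins, ligands and complexes:
# an atoms tibble plus a bonds tibble.  Atom indices are 0-based nowhere:
# everything user-facing and internal is 1-based R indexing; file formats
# (PDB/SDF) are 1-based anyway.

.origin_tags <- c("POI", "E3L", "WARHEAD", "LINKER", "LE3", "SOLVENT")

#' Construct a molecular structure
#'
#' The central container of the package: an ordered atom table and a unique,
#' symmetric-free bond list. Used for proteins, small molecules, half
#' complexes and full ternary complexes alike.
#'
#' @param atoms a data frame with at least `element`, `x`, `y`, `z`; optional
#'   columns `name` (PDB atom name), `formal_charge`, `partial_charge`,
#'   `residue_name`, `residue_number`, `chain_id`, `origin_tag` are filled
#'   with defaults when absent.
#' @param bonds a data frame with columns `i`, `j` (1-based atom indices) and
#'   optionally `order` (1, 2, 3; default 1). Each bonded pair is stored once
#'   with `i < j`.
#' @param title free-text title.
#' @return an object of class `mol_structure` with elements `atoms` (tibble),
#'   `bonds` (tibble) and `title`.
#' @examples
#' m <- mol_structure(data.frame(element = c("C", "C"),
#'                               x = c(0, 1.52), y = 0, z = 0),
#'                    bonds = data.frame(i = 1, j = 2))
#' n_atoms(m)
#' @export
mol_structure <- function(atoms, bonds = NULL, title = "") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  defaults <- list(
    name = NA_character_, formal_charge = 0L, partial_charge = 0,
    residue_name = "", residue_number = NA_integer_, chain_id = "",
    origin_tag = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- rep(defaults[[col]], length.out = max(n, 1))[seq_len(n)]
  }
  atoms$element <- .norm_element(atoms$element)
  if (n > 0 && !all(is_valid_element(atoms$element))) {
    bad <- unique(atoms$element[!is_valid_element(atoms$element)])
    stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (n > 0 && !all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom coordinates must be finite")
  }
  bad_tag <- !is.na(atoms$origin_tag) & !atoms$origin_tag %in% .origin_tags
  if (any(bad_tag)) {
    stop("invalid origin_tag(s): ", paste(unique(atoms$origin_tag[bad_tag]), collapse = ", "))
  }
  atoms <- atoms[, c("element", "x", "y", "z", "name", "formal_charge",
                     "partial_charge", "residue_name", "residue_number",
                     "chain_id", "origin_tag")]

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$i < 1L | bonds$j < 1L | bonds$i > n | bonds$j > n)) {
      stop("bond indices out of range 1..", n)
    }
    ij <- cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bonds$i <- ij[, 1]; bonds$j <- ij[, 2]
    dup <- duplicated(paste(bonds$i, bonds$j))
    bonds <- bonds[!dup, c("i", "j", "order")]
    bonds <- dplyr::arrange(bonds, .data$i, .data$j)
  }
  structure(list(atoms = atoms, bonds = bonds, title = as.character(title)[1]),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("<mol_structure>", if (nzchar(x$title)) x$title else "", "\n")
  cat("  atoms: ", n_atoms(x), " (", sum(is_heavy(x)), " heavy), bonds: ",
      nrow(x$bonds), "\n", sep = "")
  tags <- table(x$atoms$origin_tag, useNA = "no")
  if (length(tags)) {
    cat("  tags:  ", paste(names(tags), tags, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param m a `mol_structure`.
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Atom coordinates as a matrix
#' @param m a `mol_structure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(m) {
  cbind(x = unname(m$atoms$x), y = unname(m$atoms$y), z = unname(m$atoms$z))
}

#' Replace atom coordinates
#' @param m a `mol_structure`.
#' @param value numeric n x 3 matrix.
#' @export
`coords<-` <- function(m, value) {
  stopifnot(is.matrix(value), nrow(value) == n_atoms(m), ncol(value) == 3)
  m$atoms$x <- value[, 1]; m$atoms$y <- value[, 2]; m$atoms$z <- value[, 3]
  m
}

#' Heavy-atom indicator
#' @param m a `mol_structure`.
#' @return logical vector, `TRUE` for non-hydrogen atoms.
#' @export
is_heavy <- function(m) m$atoms$element != "H"

#' Extract a subset of atoms, keeping internal bonds
#'
#' @param m a `mol_structure`.
#' @param idx integer atom indices (1-based) to keep, in the order given.
#' @return a `mol_structure`; bonds between kept atoms are reindexed, bonds to
#'   dropped atoms are removed.
#' @export
subset_structure <- function(m, idx) {
  idx <- as.integer(idx)
  stopifnot(!anyDuplicated(idx), all(idx >= 1L & idx <= n_atoms(m)))
  map <- integer(n_atoms(m)); map[idx] <- seq_along(idx)
  b <- m$bonds[m$bonds$i %in% idx & m$bonds$j %in% idx, ]
  b$i <- map[b$i]; b$j <- map[b$j]
  mol_structure(m$atoms[idx, ], b, title = m$title)
}

#' Concatenate two structures into one
#'
#' Atom order is `a` then `b`; `b`'s bond indices are shifted.
#' @param a,b `mol_structure` objects.
#' @param title title of the result.
#' @return a `mol_structure`.
#' @export
combine_structures <- function(a, b, title = a$title) {
  off <- n_atoms(a)
  bonds_b <- b$bonds
  if (nrow(bonds_b)) { bonds_b$i <- bonds_b$i + off; bonds_b$j <- bonds_b$j + off }
  mol_structure(dplyr::bind_rows(a$atoms, b$atoms),
                dplyr::bind_rows(a$bonds, bonds_b), title = title)
}

#' Add a covalent bond
#' @param m a `mol_structure`.
#' @param i,j 1-based atom indices.
#' @param order bond order.
#' @return the modified structure.
#' @export
add_bond <- function(m, i, j, order = 1L) {
  mol_structure(m$atoms,
                dplyr::bind_rows(m$bonds,
                                 tibble::tibble(i = as.integer(i), j = as.integer(j),
                                                order = as.integer(order))),
                title = m$title)
}

#' Set the provenance tag of a set of atoms
#' @param m a `mol_structure`.
#' @param tag one of `"POI"`, `"E3L"`, `"WARHEAD"`, `"LINKER"`, `"LE3"`,
#'   `"SOLVENT"`.
#' @param idx atom indices (default: all atoms).
#' @return the modified structure.
#' @export
set_origin_tag <- function(m, tag, idx = seq_len(n_atoms(m))) {
  tag <- match.arg(tag, .origin_tags)
  m$atoms$origin_tag[idx] <- tag
  m
}

# adjacency list (list of integer vectors) from the bond table
.adjacency <- function(m) {
  adj <- vector("list", n_atoms(m))
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# 1-2 and 1-3 pair keys ("i:j", i<j) for nonbonded exclusions
.excluded_pairs <- function(m) {
  b <- m$bonds
  if (!nrow(b)) return(character())
  p12 <- paste(b$i, b$j, sep = ":")
  adj <- .adjacency(m)
  p13 <- character()
  for (c_at in seq_along(adj)) {
    nb <- adj[[c_at]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13 <- c(p13, paste(cmb[1, ], cmb[2, ], sep = ":"))
    }
  }
  unique(c(p12, p13))
}
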