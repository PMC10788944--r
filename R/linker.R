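# Linker construction (full-length, de novo) and attachment to a posed
# protein-moiety complex, keeping the moiety pose untouched.

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit vector of the "open" direction at atom `a` (opposite the mean of its
# existing bond directions); `fallback` used when degenerate
.open_direction <- function(m, a, fallback = c(1, 0, 0)) {
  xyz <- coords(m)
  nb <- .adjacency(m)[[a]]
  if (!length(nb)) return(fallback / sqrt(sum(fallback^2)))
  dirs <- sweep(xyz[nb, , drop = FALSE], 2, xyz[a, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  s <- -colSums(dirs)
  if (sqrt(sum(s^2)) < 1e-6) {
    # linear/symmetric environment: any perpendicular to the first bond
    b1 <- dirs[1, ]
    p <- c(-b1[2], b1[1], 0)
    if (sqrt(sum(p^2)) < 1e-6) p <- c(0, -b1[3], b1[2])
    return(p / sqrt(sum(p^2)))
  }
  s / sqrt(sum(s^2))
}

# rotation matrix mapping unit vector a onto unit vector b
.align_rotation <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- c(-a[2], a[1], 0)
    if (sqrt(sum(p^2)) < 1e-6) p <- c(0, -a[3], a[2])
    return(rotation_about_axis(p, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

#' Add explicit hydrogens at standard geometry
#'
#' Fills each heavy atom's valence (element valence plus formal charge) with
#' hydrogens placed along the most open directions at ideal bond length.
#' Junction atoms can be given open valences that are left uncapped.
#'
#' @param m a `mol_structure`.
#' @param open_valences named-free integer vector of atom indices; each
#'   listed atom keeps one valence open per occurrence.
#' @return a `mol_structure` with hydrogens appended after the input atoms.
#' @export
add_hydrogens <- function(m, open_valences = integer()) {
  adj <- .adjacency(m)
  b <- m$bonds
  for (a in seq_len(n_atoms(m))) {
    if (m$atoms$element[a] == "H") next
    used <- if (nrow(b)) sum(b$order[b$i == a | b$j == a]) else 0
    target <- element_param(m$atoms$element[a], "valence") +
      m$atoms$formal_charge[a]
    n_h <- target - used - sum(open_valences == a)
    if (n_h <= 0) next
    for (h in seq_len(n_h)) {
      d <- .open_direction(m, a)
      pos <- coords(m)[a, ] + d * ideal_bond_length(m$atoms$element[a], "H")
      m <- combine_structures(
        m, mol_structure(tibble::tibble(element = "H", x = pos[1], y = pos[2],
                                        z = pos[3],
                                        origin_tag = m$atoms$origin_tag[a])))
      m <- add_bond(m, a, n_atoms(m))
    }
  }
  m
}

# audit: smallest nonbonded (non-1-2/1-3) heavy-atom distance
.min_nonbonded_dist <- function(m) {
  hv <- which(is_heavy(m))
  if (length(hv) < 2) return(Inf)
  xyz <- coords(m)[hv, , drop = FALSE]
  pr <- close_pairs(xyz, 3.0)
  if (!nrow(pr)) return(Inf)
  excl <- .excluded_pairs(m)
  gi <- hv[pr[, 1]]; gj <- hv[pr[, 2]]
  keep <- !(paste(pmin(gi, gj), pmax(gi, gj), sep = ":") %in% excl)
  if (!any(keep)) return(Inf)
  min(sqrt(rowSums((xyz[pr[keep, 1], , drop = FALSE] -
                      xyz[pr[keep, 2], , drop = FALSE])^2)))
}

#' Build one 3D conformer of a linker
#'
#' Embeds an acyclic linker fragment in 3D from ideal internal coordinates
#' (bond lengths from the force-field table, tetrahedral/trigonal angles,
#' anti-preferred torsions). If the first all-anti attempt leaves a steric
#' overlap, torsions are resampled from the staggered set with a seeded RNG,
#' up to 50 retries. Hydrogens are added everywhere except at the junction
#' open valences. Deterministic for a fixed seed.
#'
#' @param linker a `mol_structure` (e.g. `$linker` of
#'   [decompose_protac()]); must be acyclic and connected.
#' @param seed integer RNG seed.
#' @param junction_atoms atom indices carrying an open valence (left
#'   unprotonated).
#' @return a `mol_structure` with 3D coordinates, hydrogens appended.
#' @export
build_linker_3d <- function(linker, seed = 1L, junction_atoms = integer()) {
  stopifnot(inherits(linker, "mol_structure"), n_atoms(linker) >= 1)
  if (length(ring_bonds(linker))) {
    stop("the built-in conformer builder supports acyclic linkers only")
  }
  if (length(graph_components(linker)) != 1) stop("linker must be connected")
  n <- n_atoms(linker)
  el <- linker$atoms$element
  adj <- .adjacency(linker)

  root <- if (length(junction_atoms)) junction_atoms[1] else 1L
  # BFS order and parents
  parent <- rep(NA_integer_, n); ord <- integer(0); queue <- root
  seen <- logical(n); seen[root] <- TRUE
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]; ord <- c(ord, a)
    for (nb in sort(adj[[a]])) if (!seen[nb]) {
      seen[nb] <- TRUE; parent[nb] <- a; queue <- c(queue, nb)
    }
  }

  place <- function(torsion_of) {
    xyz <- matrix(NA_real_, n, 3)
    placed <- logical(n)
    nth_child <- integer(n)   # how many children already placed per parent
    for (a in ord) {
      if (a == root) { xyz[a, ] <- 0; placed[a] <- TRUE; next }
      p <- parent[a]
      r0 <- ideal_bond_length(el[p], el[a])
      g <- parent[p]
      if (is.na(g)) {
        # second shell: along x, or at theta0 in the xy-plane for siblings
        k <- nth_child[p]; nth_child[p] <- k + 1L
        th <- 109.47 * pi / 180
        dir <- if (k == 0) c(1, 0, 0) else
          c(cos(th), sin(th), 0) |>
          (\(v) as.numeric(rotation_about_axis(c(1, 0, 0),
                                               2 * pi * (k - 1) / 3) %*% v))()
        xyz[a, ] <- xyz[p, ] + r0 * dir
      } else {
        gg <- parent[g]
        ref <- if (!is.na(gg)) xyz[gg, ] else xyz[g, ] + c(0, 1, 0)
        k <- nth_child[p]; nth_child[p] <- k + 1L
        tau <- torsion_of[a] + k * 2 * pi / 3
        th <- 109.47 * pi / 180
        # NeRF placement: bond p->a with angle th at p, torsion tau about g-p
        bc <- xyz[p, ] - xyz[g, ]; bc <- bc / sqrt(sum(bc^2))
        ab <- xyz[g, ] - ref
        nrm <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
                 ab[1] * bc[2] - ab[2] * bc[1])
        if (sqrt(sum(nrm^2)) < 1e-8) nrm <- c(0, 0, 1)
        nrm <- nrm / sqrt(sum(nrm^2))
        m_ <- c(nrm[2] * bc[3] - nrm[3] * bc[2], nrm[3] * bc[1] - nrm[1] * bc[3],
                nrm[1] * bc[2] - nrm[2] * bc[1])
        d2 <- c(-r0 * cos(th), r0 * sin(th) * cos(tau), r0 * sin(th) * sin(tau))
        xyz[a, ] <- xyz[p, ] + d2[1] * bc + d2[2] * m_ + d2[3] * nrm
      }
      placed[a] <- TRUE
    }
    xyz
  }

  out <- with_seed(seed, {
    res <- NULL
    for (try_i in 0:50) {
      tors <- if (try_i == 0) rep(pi, n) else
        sample(c(pi, pi / 3, -pi / 3), n, replace = TRUE) +
        stats::runif(n, -0.05, 0.05)
      xyz <- place(tors)
      cand <- linker
      coords(cand) <- xyz
      ok_bonds <- {
        d <- sqrt(rowSums((xyz[cand$bonds$i, , drop = FALSE] -
                             xyz[cand$bonds$j, , drop = FALSE])^2))
        all(d > 0.8 & d < 1.9)
      }
      if (ok_bonds && .min_nonbonded_dist(cand) >= 1.5) { res <- cand; break }
    }
    res
  })
  if (is.null(out)) {
    stop("conformer embedding failed after 50 seeded retries")
  }
  out <- set_origin_tag(out, "LINKER")
  add_hydrogens(out, open_valences = junction_atoms)
}

#' Attach a built linker to a protein-moiety half input
#'
#' Rigidly places the linker so that the new junction bond has the ideal
#' length for its element pair, the linker's open valence points back at the
#' moiety attachment atom, and the torsion about the new bond (12 evenly
#' spaced candidates) minimises steric overlap with the existing atoms.
#' Protein and moiety coordinates are untouched. If every candidate torsion
#' leaves a hard clash (heavy-heavy < 1.5 Angstrom), the best candidate is
#' kept with a warning (minimization resolves it downstream).
#'
#' @param half a tagged protein+moiety `mol_structure`
#'   (from [make_half_input()]).
#' @param linker3d a built linker ([build_linker_3d()]).
#' @param junction `c(moiety = atom index in half, linker = atom index in
#'   linker3d)` of the new bond.
#' @param junction_distal linker3d atom index of the far-end attachment atom
#'   (bonds to the other moiety after merging).
#' @param seed integer; reserved for candidate sampling, the default grid is
#'   deterministic.
#' @param side `"POI_SIDE"` or `"E3_SIDE"`.
#' @return a `half_complex`.
#' @export
attach_linker <- function(half, linker3d, junction, junction_distal = NA_integer_,
                          seed = 1L, side = c("POI_SIDE", "E3_SIDE")) {
  side <- match.arg(side)
  m_at <- as.integer(junction[["moiety"]]); l_at <- as.integer(junction[["linker"]])
  stopifnot(m_at >= 1, m_at <= n_atoms(half),
            l_at >= 1, l_at <= n_atoms(linker3d))

  dir_m <- .open_direction(half, m_at,
                           fallback = coords(half)[m_at, ] - colMeans(coords(half)))
  r0 <- ideal_bond_length(half$atoms$element[m_at], linker3d$atoms$element[l_at])
  target_pos <- coords(half)[m_at, ] + r0 * dir_m

  dir_l <- .open_direction(linker3d, l_at)
  rot0 <- .align_rotation(dir_l, -dir_m)
  lxyz0 <- sweep(coords(linker3d), 2, coords(linker3d)[l_at, ])
  lxyz0 <- lxyz0 %*% t(rot0)

  half_xyz <- coords(half)
  half_heavy <- which(is_heavy(half))
  l_heavy <- which(is_heavy(linker3d))
  rv_half <- element_param(half$atoms$element[half_heavy], "rvdw")
  rv_link <- element_param(linker3d$atoms$element[l_heavy], "rvdw")

  best <- NULL
  for (k in 0:11) {
    rk <- rotation_about_axis(dir_m, k * pi / 6)
    xyz_k <- sweep(lxyz0 %*% t(rk), 2, target_pos, `+`)
    lx <- xyz_k[l_heavy, , drop = FALSE]
    dmin <- Inf; pen <- 0
    for (q in seq_along(half_heavy)) {
      hq <- half_heavy[q]
      if (hq == m_at) next     # bonded to the junction atom
      dd <- sqrt(rowSums(sweep(lx, 2, half_xyz[hq, ])^2))
      ov <- pmax(0, 0.85 * (rv_link + rv_half[q]) - dd)
      pen <- pen + sum(ov^2)
      dmin <- min(dmin, min(dd))
    }
    if (is.null(best) || pen < best$pen - 1e-12) {
      best <- list(k = k, xyz = xyz_k, pen = pen, dmin = dmin)
    }
  }
  if (best$dmin < 1.5) {
    warning("all candidate torsions leave a hard clash; keeping the best ",
            "candidate (stage minimization will resolve it)")
  }
  linker_placed <- linker3d
  coords(linker_placed) <- best$xyz
  np <- n_atoms(half)
  merged <- combine_structures(half, linker_placed, title = half$title)
  merged <- add_bond(merged, m_at, np + l_at)
  new_half_complex(merged, side,
                   linker_junction_local = np + l_at,
                   linker_junction_distal = if (is.na(junction_distal))
                     NA_integer_ else np + as.integer(junction_distal),
                   moiety_junction_atom = m_at)
}

#' Construct a half-complex object
#'
#' @param structure a tagged `mol_structure` (protein + moiety + linker).
#' @param side `"POI_SIDE"` or `"E3_SIDE"`.
#' @param linker_junction_local index of the linker atom bonded to this
#'   half's moiety.
#' @param linker_junction_distal index of the linker atom that bonds the
#'   other moiety after merging.
#' @param moiety_junction_atom index of the moiety attachment atom.
#' @return a `half_complex`: list with `structure`, `protein_atoms`,
#'   `moiety_atoms`, `linker_atoms`, `side` and the junction bookkeeping.
#' @export
new_half_complex <- function(structure, side = c("POI_SIDE", "E3_SIDE"),
                             linker_junction_local = NA_integer_,
                             linker_junction_distal = NA_integer_,
                             moiety_junction_atom = NA_integer_) {
  side <- match.arg(side)
  tags <- structure$atoms$origin_tag
  prot_tags <- if (side == "POI_SIDE") "POI" else "E3L"
  moi_tags <- if (side == "POI_SIDE") "WARHEAD" else "LE3"
  obj <- list(structure = structure,
              protein_atoms = which(tags %in% prot_tags),
              moiety_atoms = which(tags %in% moi_tags),
              linker_atoms = which(tags == "LINKER"),
              side = side,
              linker_junction_local = linker_junction_local,
              linker_junction_distal = linker_junction_distal,
              moiety_junction_atom = moiety_junction_atom)
  n <- n_atoms(structure)
  if (length(c(obj$protein_atoms, obj$moiety_atoms, obj$linker_atoms)) != n) {
    stop("origin tags must partition the half-complex atoms into ",
         "protein/moiety/linker")
  }
  class(obj) <- "half_complex"
  obj
}

#' @export
print.half_complex <- function(x, ...) {
  cat("<half_complex>", x$side, "| protein:", length(x$protein_atoms),
      "moiety:", length(x$moiety_atoms), "linker:", length(x$linker_atoms),
      "atoms\n")
  invisible(x)
}
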