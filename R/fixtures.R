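# Seeded generator of fully synthetic toy systems: polyalanine pocket cages,
# small branched guest ligands, zig-zag linkers, and pre-assembled reference
# ternary complexes with known ground truth.  Geometry is built from the
# force field's own ideal internal coordinates so that CLEAN fixtures start
# at (or very near) an energy minimum -- that is what makes exact
# ground-truth recovery a meaningful contract.

.flavors <- c("CLEAN", "CLASHED", "SYMMETRIC_LINKER", "STRAINED_JUNCTION")

#' Specification of a synthetic toy system
#'
#' @param seed integer RNG seed (drives residue-placement jitter and the
#'   emitted rigid displacement of the E3 half).
#' @param pocket_depth radial distance (Angstrom) from the pocket centre to
#'   the inward-pointing C-beta atoms of the cage residues.
#' @param linker_length number of linker heavy atoms (>= 1).
#' @param perturbation magnitude (Angstrom) of the known rigid displacement
#'   applied to the emitted E3 half; the recovery target is the unperturbed
#'   truth.
#' @param flavor `"CLEAN"`, `"CLASHED"`, `"SYMMETRIC_LINKER"` or
#'   `"STRAINED_JUNCTION"`.
#' @param n_res alanine residues per pocket cage.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, pocket_depth = 4.5, linker_length = 6L,
                         perturbation = 0, flavor = "CLEAN", n_res = 8L) {
  flavor <- match.arg(flavor, .flavors)
  stopifnot(linker_length >= 1, perturbation >= 0, pocket_depth > 3,
            n_res >= 4)
  structure(list(seed = as.integer(seed), pocket_depth = pocket_depth,
                 linker_length = as.integer(linker_length),
                 perturbation = perturbation, flavor = flavor,
                 n_res = as.integer(n_res)),
            class = "fixture_spec")
}

# alanine heavy-atom template at the force field's ideal internal
# coordinates (bond r0 and theta0 exactly); columns x,y,z; order N,CA,C,O,CB
.ala_template <- function() {
  n <- c(0, 0, 0)
  ca <- c(1.47, 0, 0)
  th <- (180 - 109.47) * pi / 180
  c_ <- ca + 1.52 * c(cos(th), sin(th), 0)
  u_ca <- (ca - c_) / sqrt(sum((ca - c_)^2))
  rot120 <- rotation_about_axis(c(0, 0, 1), 120 * pi / 180)
  o <- c_ + 1.30 * as.numeric(rot120 %*% u_ca)
  u1 <- (n - ca) / 1.47
  u2 <- (c_ - ca) / 1.52
  b <- -(u1 + u2); b <- b / sqrt(sum(b^2))
  p <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
         u1[1] * u2[2] - u1[2] * u2[1])
  p <- p / sqrt(sum(p^2))
  phi <- 54.7356 * pi / 180
  cb <- ca + 1.52 * (b * cos(phi) - p * sin(phi))
  rbind(N = n, CA = ca, C = c_, O = o, CB = cb)
}

# one alanine residue as a mol_structure
.ala_residue <- function(xyz, resno, chain, tag) {
  mol_structure(
    tibble::tibble(element = c("N", "C", "C", "O", "C"),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   name = c("N", "CA", "C", "O", "CB"),
                   residue_name = "ALA", residue_number = resno,
                   chain_id = chain, origin_tag = tag),
    tibble::tibble(i = c(1, 2, 3, 2), j = c(2, 3, 4, 5),
                   order = c(1L, 1L, 2L, 1L)))
}

# polyalanine cage: residues on a spherical cap around `center`, C-beta
# pointing at the pocket, opening along `axis`.  Residues are placed as
# rigid ideal-geometry copies (not peptide-bonded) so the cage sits at the
# force field's bonded minimum by construction.
.make_cage <- function(center, axis, spec, chain, tag, res_offset = 0L) {
  axis <- axis / sqrt(sum(axis^2))
  n_res <- spec$n_res
  n_ring1 <- min(6L, n_res - 2L)
  theta <- c(rep(118, n_ring1), rep(152, n_res - n_ring1)) * pi / 180
  phi <- c(seq(0, 300, length.out = n_ring1 + 1)[seq_len(n_ring1)],
           seq(30, 330, length.out = n_res - n_ring1 + 1)[seq_len(n_res - n_ring1)]) * pi / 180
  jit_th <- stats::runif(n_res, -3, 3) * pi / 180
  jit_ph <- stats::runif(n_res, -4, 4) * pi / 180
  roll <- stats::runif(n_res, 0, 2 * pi)
  # orthonormal frame with axis as z
  zv <- axis
  xv <- if (abs(zv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xv <- xv - sum(xv * zv) * zv; xv <- xv / sqrt(sum(xv^2))
  yv <- c(zv[2] * xv[3] - zv[3] * xv[2], zv[3] * xv[1] - zv[1] * xv[3],
          zv[1] * xv[2] - zv[2] * xv[1])
  tmpl <- .ala_template()
  v_out <- (tmpl["CA", ] - tmpl["CB", ]) / 1.52
  dirs <- vector("list", n_res)
  blocks <- vector("list", n_res)
  depth <- rep(spec$pocket_depth, n_res)
  for (k in seq_len(n_res)) {
    th <- theta[k] + jit_th[k]; ph <- phi[k] + jit_ph[k]
    d <- sin(th) * cos(ph) * xv + sin(th) * sin(ph) * yv + cos(th) * zv
    dirs[[k]] <- d
    rot <- rotation_about_axis(d, roll[k]) %*% .align_rotation(v_out, d)
    blocks[[k]] <- sweep(tmpl, 2, tmpl["CB", ]) %*% t(rot)
  }
  place <- function() lapply(seq_len(n_res), function(k)
    sweep(blocks[[k]], 2, center + depth[k] * dirs[[k]], `+`))
  # deterministic repair: rigidly push residues outward along their own
  # axis until no inter-residue heavy-atom pair is tighter than 3.1 A
  for (iter in 1:60) {
    xyzs <- place()
    worst <- NULL
    for (a in seq_len(n_res - 1)) for (b in (a + 1):n_res) {
      dm <- min(sqrt(pmax(outer(rowSums(xyzs[[a]]^2), rowSums(xyzs[[b]]^2), `+`) -
                            2 * tcrossprod(xyzs[[a]], xyzs[[b]]), 0)))
      if (dm < 3.1 && (is.null(worst) || dm < worst$dm)) {
        worst <- list(a = a, b = b, dm = dm)
      }
    }
    if (is.null(worst)) break
    depth[worst$b] <- depth[worst$b] + 0.3
  }
  xyzs <- place()
  cage <- NULL
  for (k in seq_len(n_res)) {
    res <- .ala_residue(xyzs[[k]], res_offset + k, chain, tag)
    cage <- if (is.null(cage)) res else combine_structures(cage, res)
  }
  cage
}

# signed dihedral angle (radians) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# branched 4-carbon guest: central atom, junction atom along `axis`, two
# flanking atoms pointing away from the junction.  When `far_atom` (the
# chain atom beyond the junction) is given, the flank azimuth is chosen so
# the flank-center-junction-chain torsions sit in a staggered minimum.
# Returns list(structure, junction = index of the open atom).
.make_guest <- function(center, axis, tag, far_atom = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  th <- 109.47 * pi / 180
  e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2], axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  flank_dir <- function(az) {
    cos(th) * axis + sin(th) * (cos(az) * e1 + sin(az) * e2)
  }
  junction <- center + 1.52 * axis
  best_az <- 0
  if (!is.null(far_atom)) {
    obj <- vapply(seq(0, 2 * pi, length.out = 121)[-121], function(az) {
      sum(vapply(c(az, az + 2 * pi / 3), function(a) {
        1 + cos(3 * .dihedral(far_atom, junction, center,
                              center + 1.52 * flank_dir(a)))
      }, numeric(1)))
    }, numeric(1))
    best_az <- seq(0, 2 * pi, length.out = 121)[-121][which.min(obj)]
  }
  xyz <- rbind(center, junction,
               center + 1.52 * flank_dir(best_az),
               center + 1.52 * flank_dir(best_az + 2 * pi / 3))
  st <- mol_structure(
    tibble::tibble(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   residue_name = "", origin_tag = tag),
    tibble::tibble(i = c(1, 1, 1), j = c(2, 3, 4)))
  list(structure = st, junction = 2L, center_atom = 1L)
}

# direction of the k-th bond (1-based) of an ideal all-anti zig-zag chain
# growing along `axis` in the axis/side plane; every bond angle tetrahedral
.zigzag_bond_dir <- function(k, axis, side) {
  s <- sin(70.53 * pi / 180); c0 <- cos(70.53 * pi / 180)
  if (k %% 2 == 0) return(axis)
  sgn <- if (((k - 1) / 2) %% 2 == 0) 1 else -1
  sgn * s * side + c0 * axis
}

# zig-zag chain coordinates: n atoms continuing from `start` (the atom the
# chain bonds to, whose own previous bond points along `axis`); bond_len[k]
# is the length of the k-th bond
.zigzag_coords <- function(n, start, axis, side, bond_len = rep(1.52, n)) {
  axis <- axis / sqrt(sum(axis^2))
  side <- side - sum(side * axis) * axis; side <- side / sqrt(sum(side^2))
  out <- matrix(NA_real_, n, 3)
  pos <- start
  for (k in seq_len(n)) {
    pos <- pos + bond_len[k] * .zigzag_bond_dir(k, axis, side)
    out[k, ] <- pos
  }
  out
}

#' Generate one toy half-complex with ground truth
#'
#' Deterministic for a fixed spec: a polyalanine pocket cage, a branched
#' guest moiety bound at the pocket centre, and the full-length linker
#' attached at the moiety junction. `side = "POI_SIDE"` yields the
#' POI-warhead half, `side = "E3_SIDE"` the E3L-L^E3 half.
#'
#' @param spec a [fixture_spec()].
#' @param side `"POI_SIDE"` or `"E3_SIDE"`.
#' @return a `half_complex`; attribute `ground_truth` holds the truth
#'   coordinates and the rigid displacement applied (identity for the POI
#'   side).
#' @export
make_toy_half <- function(spec, side = c("POI_SIDE", "E3_SIDE")) {
  side <- match.arg(side)
  tc <- make_toy_tc(spec)
  if (side == "POI_SIDE") tc$poi_half else tc$e3_half
}

#' Generate a toy ternary complex with known ground truth
#'
#' Builds one consistent geometry (`truth_tc`): POI cage + warhead at the
#' origin, an ideal zig-zag linker along +z, and the E3 cage + L^E3 at the
#' far end. The two emitted halves each carry a full copy of the linker;
#' the E3 half is displaced by a seeded rigid transform of magnitude
#' `perturbation`, so the assembly pipeline's recovery target is `truth_tc`.
#'
#' Flavors: `CLEAN` (clash-free, asymmetric linker), `CLASHED` (one cage
#' residue pushed into the warhead), `SYMMETRIC_LINKER` (all-carbon linker,
#' junction anchors left unset so the mapping ambiguity branch runs),
#' `STRAINED_JUNCTION` (L^E3-side junction bond stretched to 2.2 Angstrom).
#'
#' @param spec a [fixture_spec()].
#' @return list with `poi_half`, `e3_half` (`half_complex`), `truth_tc`
#'   (`ternary_complex`) and `e3_displacement` (the applied
#'   `rigid_transform`).
#' @export
make_toy_tc <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  # the expensive relax + pipeline run only depends on seed/geometry/linker
  # chemistry; CLASHED and STRAINED_JUNCTION defects and the rigid
  # perturbation are cheap post-hoc edits of the shared base build
  base_spec <- spec
  base_spec$perturbation <- 0
  if (spec$flavor %in% c("CLASHED", "STRAINED_JUNCTION")) {
    base_spec$flavor <- "CLEAN"
  }
  key <- paste(unlist(base_spec), collapse = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- .build_toy_tc(base_spec)
  }
  base <- .fixture_cache[[key]]
  poi_half <- base$poi_half
  e3_half <- base$e3_half
  truth_tc <- base$truth_tc

  if (spec$flavor == "CLASHED") {
    # push the first POI cage residue rigidly toward the warhead so its
    # C-beta ends ~2.0 A from the nearest guest atom (clash by design)
    xyz <- coords(poi_half$structure)
    cb <- xyz[5, ]
    guest_xyz <- xyz[poi_half$moiety_atoms, , drop = FALSE]
    nearest <- guest_xyz[which.min(sqrt(rowSums(sweep(guest_xyz, 2, cb)^2))), ]
    v <- nearest - cb; dn <- sqrt(sum(v^2))
    shift <- (dn - 2.0) * v / dn
    xyz[1:5, ] <- sweep(xyz[1:5, , drop = FALSE], 2, shift, `+`)
    coords(poi_half$structure) <- xyz
  }
  if (spec$flavor == "STRAINED_JUNCTION") {
    # stretch the L^E3-linker junction bond to 2.2 A by rigidly shifting
    # the E3 cage + moiety away from this half's linker copy
    xyz <- coords(e3_half$structure)
    lk <- xyz[e3_half$linker_junction_local, ]
    mj <- xyz[e3_half$moiety_junction_atom, ]
    v <- mj - lk; dn <- sqrt(sum(v^2))
    shift <- (2.2 - dn) * v / dn
    idx <- sort(c(e3_half$protein_atoms, e3_half$moiety_atoms))
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, `+`)
    coords(e3_half$structure) <- xyz
  }

  # displace the emitted E3 half by a known, seeded rigid transform
  tf <- if (spec$perturbation > 0) {
    with_seed(spec$seed + 421L, {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- min(spec$perturbation * 9, 170) * pi / 180
      rot <- rotation_about_axis(ax, ang)
      ctr <- colMeans(coords(e3_half$structure))
      tv <- stats::rnorm(3); tv <- tv / sqrt(sum(tv^2))
      trans <- as.numeric(ctr - rot %*% ctr) + spec$perturbation * tv
      new_rigid_transform(rot, trans)
    })
  } else identity_transform()
  e3_half$structure <- apply_transform(e3_half$structure, tf)

  attr(poi_half, "ground_truth") <- list(displacement = identity_transform())
  attr(e3_half, "ground_truth") <- list(
    displacement = tf, truth_coords = coords(truth_tc$structure))
  list(poi_half = poi_half, e3_half = e3_half, truth_tc = truth_tc,
       e3_displacement = tf)
}

# construction is minimization-heavy and fully deterministic, so built
# fixtures are memoised per spec within a session
.fixture_cache <- new.env(parent = emptyenv())

.build_toy_tc <- function(spec) {
  with_seed(spec$seed, {
    nl <- spec$linker_length
    el_link <- rep("C", nl)
    if (spec$flavor != "SYMMETRIC_LINKER" && nl >= 3) el_link[2] <- "O"
    chain_el <- c("C", el_link)          # junction atom, then the linker
    blen <- ideal_bond_length(chain_el[seq_len(nl)], chain_el[seq_len(nl) + 1])

    # warhead at the origin, junction atom along +z; flanks staggered
    # against the first linker atom
    wj_pos <- c(0, 0, 1.52)
    l1_pos <- wj_pos + blen[1] * .zigzag_bond_dir(1, c(0, 0, 1), c(1, 0, 0))
    wh <- .make_guest(c(0, 0, 0), c(0, 0, 1), "WARHEAD", far_atom = l1_pos)
    poi_cage <- .make_cage(c(0, 0, 0), c(0, 0, 1), spec, "A", "POI")

    # linker chain continuing from the warhead junction atom
    lx <- .zigzag_coords(nl, wj_pos, c(0, 0, 1), c(1, 0, 0), bond_len = blen)
    linker <- mol_structure(
      tibble::tibble(element = el_link, x = lx[, 1], y = lx[, 2], z = lx[, 3],
                     residue_name = "", origin_tag = "LINKER"),
      if (nl > 1) tibble::tibble(i = seq_len(nl - 1), j = seq_len(nl - 1) + 1)
      else NULL)

    # L^E3 guest: junction atom continues the chain beyond the last linker atom
    dir_next <- .zigzag_bond_dir(nl + 1, c(0, 0, 1), c(1, 0, 0))
    e1 <- lx[nl, ] + 1.52 * dir_next
    dir_e0 <- .zigzag_bond_dir(nl + 2, c(0, 0, 1), c(1, 0, 0))
    e0 <- e1 + 1.52 * dir_e0
    le3 <- .make_guest(e0, -dir_e0, "LE3", far_atom = lx[nl, ])
    e3_cage <- .make_cage(e0, -dir_e0, spec, "B", "E3L", res_offset = 100L)

    # assemble the two halves (atom order: protein, moiety, linker)
    mk_half <- function(cage, guest, side) {
      st <- combine_structures(cage, guest$structure)
      moi_j <- n_atoms(cage) + guest$junction
      st <- combine_structures(st, linker)
      off <- n_atoms(cage) + n_atoms(guest$structure)
      link_idx <- off + seq_len(nl)
      if (side == "POI_SIDE") {
        st <- add_bond(st, moi_j, link_idx[1])
        loc <- link_idx[1]; dis <- link_idx[nl]
      } else {
        st <- add_bond(st, moi_j, link_idx[nl])
        loc <- link_idx[nl]; dis <- link_idx[1]
      }
      if (spec$flavor == "SYMMETRIC_LINKER") dis <- NA_integer_
      new_half_complex(st, side, linker_junction_local = loc,
                       linker_junction_distal = dis,
                       moiety_junction_atom = moi_j)
    }
    poi_half <- mk_half(poi_cage, wh, "POI_SIDE")
    e3_half <- mk_half(e3_cage, le3, "E3_SIDE")

    # truth ternary complex: POI half + trimmed E3 half, atom order matching
    # what superpose_and_merge emits
    e3_keep <- sort(c(e3_half$protein_atoms, e3_half$moiety_atoms))
    truth_struct <- combine_structures(
      poi_half$structure, subset_structure(e3_half$structure, e3_keep),
      title = sprintf("toy TC (seed %d, %s)", spec$seed, spec$flavor))
    np <- n_atoms(poi_half$structure)
    le3_anchor <- match(e3_half$moiety_junction_atom, e3_keep)
    truth_struct <- add_bond(truth_struct, poi_half$linker_atoms[nl],
                             np + le3_anchor)

    # relax the analytic assembly to the force field's own local minimum so
    # the ground truth is (near) a fixed point of unrestrained refinement
    truth_struct <- minimize_structure(
      truth_struct, mobile = seq_len(n_atoms(truth_struct)),
      config = min_config(tol = 0.02, max_iter = 4000))$structure

    # derive both emitted halves from the relaxed truth coordinates
    truth_xyz <- coords(truth_struct)
    coords(poi_half$structure) <- truth_xyz[seq_len(np), , drop = FALSE]
    e3_xyz <- rbind(truth_xyz[np + seq_along(e3_keep), , drop = FALSE],
                    truth_xyz[poi_half$linker_atoms, , drop = FALSE])
    coords(e3_half$structure) <- e3_xyz

    # the recorded ground truth is the deterministic pipeline's own output on
    # the unperturbed halves, so a perturbed run's recovery target is the
    # model the pipeline converges to rather than the raw analytic geometry
    truth_tc <- suppressMessages(suppressWarnings(
      model_ternary_complex(poi_half, e3_half)))$tc

    list(poi_half = poi_half, e3_half = e3_half, truth_tc = truth_tc)
  })
}
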