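# Light molecular-mechanics engine used for all minimization stages and for
# per-interaction energies:
#   bonds    harmonic, r0 = covalent-radii sum (order-shortened), k = 300
#   angles   harmonic, theta0 from coordination/bond-order, k = 60
#   torsions 3-fold cosine (V3/2)(1 + cos 3phi) around saturated central
#            bonds (staggered minima; keeps built anti conformers in their
#            torsional well instead of curling under dispersion)
#   LJ 12-6 on Bondi radii (rmin = Ri + Rj, eps = sqrt(ei ej))
#   Coulomb with distance-dependent dielectric eps(r) = 4r
#   harmonic positional restraints
# Energies in kcal/mol, distances in Angstrom.  1-2 and 1-3 pairs excluded
# from the nonbonded sum.

.coulomb_k <- 332.0636

#' Minimization settings
#'
#' @param restraint_k harmonic positional restraint constant,
#'   kcal/mol/Angstrom^2.
#' @param tol convergence tolerance on the projected gradient,
#'   kcal/mol/Angstrom.
#' @param max_iter maximum L-BFGS iterations per stage.
#' @param cutoff nonbonded cutoff (Angstrom) for energy evaluation.
#' @param forcefield engine name; `"tcff"` (the built-in engine) is the only
#'   value currently available, the slot fixes the engine per run.
#' @return a `min_config` list.
#' @export
min_config <- function(restraint_k = 100, tol = 0.1, max_iter = 2000,
                       cutoff = 10, forcefield = "tcff") {
  stopifnot(restraint_k >= 0, tol > 0, max_iter >= 1, cutoff > 0)
  if (!identical(forcefield, "tcff")) {
    stop("unknown force field engine: ", forcefield)
  }
  structure(list(restraint_k = restraint_k, tol = tol, max_iter = max_iter,
                 cutoff = cutoff, forcefield = forcefield),
            class = "min_config")
}

# equilibrium angle (radians) at a centre atom
.theta0 <- function(degree, max_order) {
  th <- ifelse(degree >= 4, 109.47,
        ifelse(degree == 3, ifelse(max_order >= 2, 120, 109.47),
        ifelse(max_order >= 3, 180 - 1e-4,
        ifelse(max_order == 2, 120, 109.47))))
  th * pi / 180
}

# precompute all energy terms for a structure
.ff_terms <- function(m, cutoff = 10) {
  el <- m$atoms$element
  if (!all(is_valid_element(el))) {
    bad <- which(!is_valid_element(el))[1]
    stop("force-field typing failed for atom ", bad, " (element '", el[bad], "')")
  }
  b <- m$bonds
  bonds <- list(i = b$i, j = b$j,
                r0 = ideal_bond_length(el[b$i], el[b$j], b$order),
                k = rep(300, nrow(b)))
  adj <- .adjacency(m)
  deg <- lengths(adj)
  maxord <- vapply(seq_len(n_atoms(m)), function(a) {
    k <- which(b$i == a | b$j == a)
    if (length(k)) max(b$order[k]) else 0L
  }, numeric(1))
  ai <- integer(); ac <- integer(); ak <- integer()
  for (c_at in which(deg >= 2)) {
    nb <- sort(adj[[c_at]])
    cmb <- utils::combn(nb, 2)
    ai <- c(ai, cmb[1, ]); ak <- c(ak, cmb[2, ])
    ac <- c(ac, rep(c_at, ncol(cmb)))
  }
  angles <- list(i = ai, c = ac, k = ak,
                 th0 = .theta0(deg[ac], maxord[ac]),
                 ka = rep(60, length(ac)))
  # proper torsions around single bonds between saturated centres
  ti <- integer(); tj <- integer(); tk <- integer(); tl <- integer()
  for (row in which(b$order == 1L)) {
    cj <- b$i[row]; ck <- b$j[row]
    if (maxord[cj] >= 2 || maxord[ck] >= 2) next
    for (i_at in setdiff(adj[[cj]], ck)) {
      for (l_at in setdiff(adj[[ck]], cj)) {
        if (i_at == l_at) next
        ti <- c(ti, i_at); tj <- c(tj, cj); tk <- c(tk, ck); tl <- c(tl, l_at)
      }
    }
  }
  torsions <- list(i = ti, j = tj, k = tk, l = tl,
                   v3h = rep(0.5, length(ti)))   # V3/2, kcal/mol
  out <- list(bonds = bonds, angles = angles, torsions = torsions,
              n = n_atoms(m), cutoff = cutoff,
              excl = .excluded_pairs(m),
              rvdw = .atom_rvdw(m),
              eps = element_param(el, "lj_eps"),
              q = m$atoms$partial_charge)
  .refresh_nb(out, coords(m))
}

# per-atom LJ radii: polar hydrogens (bonded to N/O/S) get a much smaller
# radius, as in standard protein force fields, so hydrogen-bond geometries
# are not spuriously penalised
.atom_rvdw <- function(m) {
  rv <- element_param(m$atoms$element, "rvdw")
  hs <- which(m$atoms$element == "H")
  if (length(hs)) {
    adj <- .adjacency(m)
    polar <- vapply(hs, function(h) {
      any(m$atoms$element[adj[[h]]] %in% c("N", "O", "S"))
    }, logical(1))
    rv[hs[polar]] <- 0.4
  }
  rv
}

# (re)build the nonbonded pair list at the given coordinates; the list goes
# stale when atoms move, so minimization refreshes it between rounds
.refresh_nb <- function(terms, xyz) {
  pr <- close_pairs(xyz, terms$cutoff)
  if (nrow(pr)) {
    keep <- !(paste(pr[, 1], pr[, 2], sep = ":") %in% terms$excl)
    pr <- pr[keep, , drop = FALSE]
  }
  terms$nb <- list(i = pr[, 1], j = pr[, 2],
                   rmin = terms$rvdw[pr[, 1]] + terms$rvdw[pr[, 2]],
                   eps = sqrt(terms$eps[pr[, 1]] * terms$eps[pr[, 2]]),
                   qq = .coulomb_k * terms$q[pr[, 1]] * terms$q[pr[, 2]])
  terms
}

# accumulate gradient contributions, aggregating duplicate atom indices
.acc <- function(G, idx, mat) {
  if (!length(idx)) return(G)
  rs <- rowsum(mat, group = idx)
  tgt <- as.integer(rownames(rs))
  G[tgt, ] <- G[tgt, , drop = FALSE] + rs
  G
}

# total energy and gradient of precomputed terms at coordinates xyz;
# restraints: list(idx, ref, k) or NULL
.ff_eval <- function(xyz, terms, restraints = NULL, want_grad = TRUE) {
  G <- if (want_grad) matrix(0, nrow(xyz), 3) else NULL
  E <- 0
  bt <- terms$bonds
  if (length(bt$i)) {
    rv <- xyz[bt$i, , drop = FALSE] - xyz[bt$j, , drop = FALSE]
    d <- sqrt(rowSums(rv^2))
    E <- E + sum(bt$k * (d - bt$r0)^2)
    if (want_grad) {
      f <- 2 * bt$k * (d - bt$r0) / pmax(d, 1e-10)
      G <- .acc(G, bt$i, rv * f)
      G <- .acc(G, bt$j, -rv * f)
    }
  }
  at <- terms$angles
  if (length(at$i)) {
    u <- xyz[at$i, , drop = FALSE] - xyz[at$c, , drop = FALSE]
    v <- xyz[at$k, , drop = FALSE] - xyz[at$c, , drop = FALSE]
    du <- sqrt(rowSums(u^2)); dv <- sqrt(rowSums(v^2))
    cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u * v) / (du * dv)))
    th <- acos(cth)
    E <- E + sum(at$ka * (th - at$th0)^2)
    if (want_grad) {
      sth <- pmax(sqrt(1 - cth^2), 1e-8)
      uh <- u / du; vh <- v / dv
      dthi <- (uh * cth - vh) / (du * sth)
      dthk <- (vh * cth - uh) / (dv * sth)
      coefs <- 2 * at$ka * (th - at$th0)
      G <- .acc(G, at$i, dthi * coefs)
      G <- .acc(G, at$k, dthk * coefs)
      G <- .acc(G, at$c, -(dthi + dthk) * coefs)
    }
  }
  tt <- terms$torsions
  if (!is.null(tt) && length(tt$i)) {
    b1 <- xyz[tt$j, , drop = FALSE] - xyz[tt$i, , drop = FALSE]
    b2 <- xyz[tt$k, , drop = FALSE] - xyz[tt$j, , drop = FALSE]
    b3 <- xyz[tt$l, , drop = FALSE] - xyz[tt$k, , drop = FALSE]
    cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                  a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                  a[, 1] * b[, 2] - a[, 2] * b[, 1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(cross(n1, n2) * (b2 / nb2)), rowSums(n1 * n2))
    E <- E + sum(tt$v3h * (1 + cos(3 * phi)))
    if (want_grad) {
      dEdphi <- -3 * tt$v3h * sin(3 * phi)
      n1sq <- pmax(rowSums(n1^2), 1e-12); n2sq <- pmax(rowSums(n2^2), 1e-12)
      dpi_ <- -n1 * (nb2 / n1sq)
      dpl <- n2 * (nb2 / n2sq)
      c12 <- rowSums(b1 * b2) / nb2^2
      c32 <- rowSums(b3 * b2) / nb2^2
      dpj <- -dpi_ * (1 + c12) + dpl * c32
      dpk <- -dpl * (1 + c32) + dpi_ * c12
      G <- .acc(G, tt$i, dpi_ * dEdphi)
      G <- .acc(G, tt$j, dpj * dEdphi)
      G <- .acc(G, tt$k, dpk * dEdphi)
      G <- .acc(G, tt$l, dpl * dEdphi)
    }
  }
  nt <- terms$nb
  if (length(nt$i)) {
    rv <- xyz[nt$i, , drop = FALSE] - xyz[nt$j, , drop = FALSE]
    d <- pmax(sqrt(rowSums(rv^2)), 0.05)
    sr6 <- (nt$rmin / d)^6
    e_lj <- nt$eps * (sr6^2 - 2 * sr6)
    e_q <- nt$qq / (4 * d^2)
    E <- E + sum(e_lj) + sum(e_q)
    if (want_grad) {
      dEdd <- -12 * nt$eps * (sr6^2 - sr6) / d - 2 * e_q / d
      f <- dEdd / d
      G <- .acc(G, nt$i, rv * f)
      G <- .acc(G, nt$j, -rv * f)
    }
  }
  if (!is.null(restraints) && length(restraints$idx)) {
    dv <- xyz[restraints$idx, , drop = FALSE] - restraints$ref
    E <- E + restraints$k * sum(dv^2)
    if (want_grad) G <- .acc(G, restraints$idx, 2 * restraints$k * dv)
  }
  list(energy = E, grad = G)
}

#' Potential energy of a structure
#'
#' Total force-field energy (bonds + angles + nonbonded; no restraints).
#'
#' @param m a `mol_structure` (or a ternary-complex / half-complex object).
#' @param config a [min_config()].
#' @return energy in kcal/mol.
#' @export
potential_energy <- function(m, config = min_config()) {
  m <- as_mol_structure(m)
  terms <- .ff_terms(m, cutoff = config$cutoff)
  .ff_eval(coords(m), terms, want_grad = FALSE)$energy
}

# coerce pipeline objects to their underlying structure
as_mol_structure <- function(x) {
  if (inherits(x, "mol_structure")) return(x)
  if (!is.null(x$structure) && inherits(x$structure, "mol_structure")) {
    return(x$structure)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a molecular structure")
}

#' Minimize a structure with mobile, restrained and fixed atoms
#'
#' Core minimizer behind every refinement stage. Atoms in `mobile` are
#' optimized freely; atoms in `restrained` are optimized under a harmonic
#' positional restraint to their starting coordinates; all remaining atoms
#' are held fixed (bitwise unchanged). Uses L-BFGS-B with analytic
#' gradients; the nonbonded pair list is built once per call.
#'
#' @param m a `mol_structure`.
#' @param mobile integer indices of freely mobile atoms.
#' @param restrained integer indices of positionally restrained atoms
#'   (disjoint from `mobile`).
#' @param config a [min_config()].
#' @return list with `structure` (minimized), `e_start`, `e_end` (kcal/mol,
#'   restraint term excluded), `converged`, and `max_moved` (largest atom
#'   displacement, Angstrom).
#' @export
minimize_structure <- function(m, mobile, restrained = integer(),
                               config = min_config()) {
  stopifnot(inherits(m, "mol_structure"))
  mobile <- as.integer(mobile); restrained <- as.integer(restrained)
  stopifnot(!anyDuplicated(c(mobile, restrained)))
  terms <- .ff_terms(m, cutoff = config$cutoff)
  xyz0 <- coords(m)
  opt_idx <- c(mobile, restrained)
  if (!length(opt_idx)) {
    return(list(structure = m, e_start = .ff_eval(xyz0, terms, want_grad = FALSE)$energy,
                e_end = .ff_eval(xyz0, terms, want_grad = FALSE)$energy,
                converged = TRUE, max_moved = 0))
  }
  restr <- if (length(restrained)) {
    list(idx = restrained, ref = xyz0[restrained, , drop = FALSE],
         k = config$restraint_k)
  } else NULL

  e_start_tot <- .ff_eval(xyz0, terms, want_grad = FALSE)$energy
  # L-BFGS-B can stop before the gradient criterion on flat landscapes, and
  # the nonbonded pair list goes stale as atoms move: restart (resetting the
  # Hessian memory) with a freshly built pair list until the gradient
  # criterion holds against the fresh list
  par <- as.numeric(xyz0[opt_idx, , drop = FALSE])
  converged <- FALSE
  xyz_cur <- xyz0
  for (round in 1:8) {
    terms <- .refresh_nb(terms, xyz_cur)
    cache <- new.env(parent = emptyenv())
    evalx <- function(par) {
      if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
      xyz <- xyz_cur
      xyz[opt_idx, ] <- matrix(par, ncol = 3)
      res <- .ff_eval(xyz, terms, restr)
      cache$par <- par; cache$res <- res
      res
    }
    fn <- function(par) evalx(par)$energy
    gr <- function(par) as.numeric(evalx(par)$grad[opt_idx, , drop = FALSE])
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$max_iter,
                                       pgtol = config$tol, factr = 10))
    moved <- max(abs(opt$par - par))
    par <- opt$par
    xyz_cur[opt_idx, ] <- matrix(par, ncol = 3)
    terms <- .refresh_nb(terms, xyz_cur)
    g_fresh <- .ff_eval(xyz_cur, terms, restr)$grad[opt_idx, , drop = FALSE]
    if (max(abs(g_fresh)) <= config$tol) { converged <- TRUE; break }
    if (moved < 1e-10) break
  }
  xyz_new <- xyz_cur
  e_end_tot <- .ff_eval(xyz_new, terms, want_grad = FALSE)$energy
  if (e_end_tot > e_start_tot) {      # minimizer contract: never go uphill
    xyz_new <- xyz0
    e_end_tot <- e_start_tot
  }
  out <- m
  coords(out) <- xyz_new
  list(structure = out, e_start = e_start_tot, e_end = e_end_tot,
       converged = converged,
       max_moved = if (length(opt_idx))
         max(sqrt(rowSums((xyz_new[opt_idx, , drop = FALSE] -
                             xyz0[opt_idx, , drop = FALSE])^2))) else 0)
  }
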