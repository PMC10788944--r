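# Solvent-accessible surface area by the Shrake-Rupley rolling-probe method:
# each heavy atom's sphere (vdW radius + probe) is sampled with a Fibonacci
# point set; the accessible fraction is the share of points not buried in
# any neighbour's sphere.

# near-uniform unit sphere points (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' @param m a `mol_structure`; hydrogens are ignored.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 256).
#' @return numeric vector of per-atom SASA (Angstrom^2) over all atoms of
#'   `m` (zero for hydrogens).
#' @export
sasa <- function(m, probe = 1.4, n_points = 256) {
  m <- as_mol_structure(m)
  out <- numeric(n_atoms(m))
  hv <- which(is_heavy(m))
  if (!length(hv)) return(out)
  xyz <- coords(m)[hv, , drop = FALSE]
  rad <- element_param(m$atoms$element[hv], "rvdw") + probe
  sph <- .fibonacci_sphere(n_points)
  maxr <- max(rad)
  nb_pairs <- close_pairs(xyz, 2 * maxr)
  nb <- vector("list", length(hv))
  if (nrow(nb_pairs)) {
    d <- sqrt(rowSums((xyz[nb_pairs[, 1], , drop = FALSE] -
                         xyz[nb_pairs[, 2], , drop = FALSE])^2))
    touch <- d < rad[nb_pairs[, 1]] + rad[nb_pairs[, 2]]
    for (k in which(touch)) {
      i <- nb_pairs[k, 1]; j <- nb_pairs[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  for (q in seq_along(hv)) {
    pts <- sweep(sph * rad[q], 2, xyz[q, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb[[q]]) {
      if (!any(acc)) break
      d2 <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- d2 > rad[j]^2
    }
    out[hv[q]] <- 4 * pi * rad[q]^2 * mean(acc)
  }
  out
}
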