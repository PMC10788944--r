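# Independent oracles used to check the implementation's operations.
# These deliberately avoid the code paths they verify.

# Brute-force rigid-fit oracle: quaternion grid over SO(3), coarse pass at
# ~10 degrees followed by a local grid at 1 degree resolution, optimal
# translation by centroid matching at each rotation.
oracle_grid_fit_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  axes_fib <- function(n) {
    k <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * k / n)
    th <- pi * (1 + sqrt(5)) * k
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  rot_mat <- function(u, ang) {
    c0 <- cos(ang); s0 <- sin(ang)
    ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                 byrow = TRUE)
    c0 * diag(3) + s0 * ux + (1 - c0) * tcrossprod(u)
  }
  eval_rot <- function(r) sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  best <- list(rmsd = Inf, axis = c(0, 0, 1), ang = 0)
  axes <- axes_fib(600)                     # ~9 degree axis spacing
  for (k in seq_len(nrow(axes))) {
    for (ang in seq(0, 180, by = 9) * pi / 180) {
      r <- eval_rot(rot_mat(axes[k, ], ang))
      if (r < best$rmsd) best <- list(rmsd = r, axis = axes[k, ], ang = ang)
    }
  }
  # local refinement: 1-degree grid around the coarse optimum
  u0 <- best$axis
  perp1 <- if (abs(u0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp1 <- perp1 - sum(perp1 * u0) * u0; perp1 <- perp1 / sqrt(sum(perp1^2))
  perp2 <- c(u0[2] * perp1[3] - u0[3] * perp1[2],
             u0[3] * perp1[1] - u0[1] * perp1[3],
             u0[1] * perp1[2] - u0[2] * perp1[1])
  step <- pi / 180
  for (da in seq(-10, 10, by = 1) * step) {
    for (t1 in seq(-10, 10, by = 2) * step) {
      for (t2 in seq(-10, 10, by = 2) * step) {
        u <- u0 + t1 * perp1 + t2 * perp2
        u <- u / sqrt(sum(u^2))
        r <- eval_rot(rot_mat(u, best$ang + da))
        if (r < best$rmsd) best$rmsd <- r
      }
    }
  }
  best$rmsd
}

# Brute-force all-pairs interaction classifier (no grid, no shared helpers)
oracle_classify_pairs <- function(m, lig, rec) {
  xyz <- coords(m)
  el <- m$atoms$element
  fc <- m$atoms$formal_charge
  # neighbour list from the bond table directly
  nbrs <- function(a) {
    b <- m$bonds
    c(b$j[b$i == a], b$i[b$j == a])
  }
  res <- list()
  for (i in lig) {
    if (el[i] == "H") next
    for (j in rec) {
      if (el[j] == "H") next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > 4.0) next
      polar_i <- el[i] %in% c("N", "O"); polar_j <- el[j] %in% c("N", "O")
      kind <- "NONBONDED"
      if (polar_i && polar_j && fc[i] * fc[j] < 0 && d <= 4.0) {
        kind <- "SALT_BRIDGE"
      } else if (polar_i && polar_j && d <= 3.5) {
        ok_dir <- function(don, acc) {
          hs <- nbrs(don); hs <- hs[el[hs] == "H"]
          any(vapply(hs, function(h) {
            v1 <- xyz[don, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
            ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                      sqrt(sum(v1^2) * sum(v2^2)))))
            ang * 180 / pi >= 120
          }, logical(1)))
        }
        if (ok_dir(i, j) || ok_dir(j, i)) kind <- "HBOND"
      }
      res[[length(res) + 1]] <- data.frame(kind = kind, ligand_atom = i,
                                           protein_atom = j, distance = d)
    }
  }
  if (!length(res)) {
    return(data.frame(kind = character(), ligand_atom = integer(),
                      protein_atom = integer(), distance = numeric()))
  }
  do.call(rbind, res)
}

# Numerical SASA oracle: latitude-longitude quadrature grid on each atom
# sphere with sin(theta) weights (independent of the Fibonacci sampler).
oracle_grid_sasa <- function(m, probe = 1.4, n_theta = 40, n_phi = 80) {
  hv <- which(is_heavy(m))
  xyz <- coords(m)[hv, , drop = FALSE]
  rad <- element_param(m$atoms$element[hv], "rvdw") + probe
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(th = th, ph = ph)
  w <- sin(grid$th)
  dirs <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  total <- 0
  for (q in seq_along(hv)) {
    pts <- sweep(dirs * rad[q], 2, xyz[q, ], `+`)
    buried <- rep(FALSE, nrow(pts))
    for (j in seq_along(hv)) {
      if (j == q) next
      buried <- buried |
        rowSums(sweep(pts, 2, xyz[j, ])^2) < rad[j]^2
    }
    frac <- sum(w[!buried]) / sum(w)
    total <- total + 4 * pi * rad[q]^2 * frac
  }
  total
}

# random connected tree molecule (for graph-identity properties)
random_tree_mol <- function(n, seed) {
  withr::with_seed(seed, {
    els <- sample(c("C", "N", "O"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
    parent <- c(NA, vapply(2:n, function(k) sample(seq_len(k - 1), 1), 1L))
    mol_structure(
      data.frame(element = els, x = rnorm(n) * 2, y = rnorm(n) * 2,
                 z = rnorm(n) * 2),
      data.frame(i = parent[-1], j = 2:n))
  })
}

# shared small fixture specs so the expensive builds are reused across files
fx_clean <- function(seed = 3, perturbation = 0) {
  make_toy_tc(fixture_spec(seed = seed, perturbation = perturbation))
}
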