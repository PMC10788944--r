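# Rigid-body superposition kernel (Kabsch, via SVD) used pipeline-wide:
# linker superposition during assembly, pose transfer, validation RMSDs.

#' Least-squares rigid superposition of two point sets
#'
#' Computes the proper rotation and translation that minimise the RMSD between
#' `mobile` and `reference` (Kabsch algorithm). Reflections are never
#' returned: when the optimal orthogonal transform would be improper, the
#' smallest singular direction is flipped.
#'
#' @param mobile,reference numeric n x 3 matrices, n >= 3, equal n.
#' @return a `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3), and `fit_rmsd` (Angstrom). The transform maps
#'   `mobile` onto `reference` as `mobile %*% t(rotation) + translation`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch_fit(p, p)$fit_rmsd
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.numeric(mobile) || !is.numeric(reference) ||
      ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("point sets must be numeric n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point sets must have equal length")
  if (n < 3) stop("at least 3 point pairs are required for a rigid fit")

  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  # collinearity check: second principal moment of either set ~ 0
  if (svd(a)$d[2] < 1e-8 * max(1, svd(a)$d[1]) ||
      svd(b)$d[2] < 1e-8 * max(1, svd(b)$d[1])) {
    stop("degenerate geometry: points are (nearly) collinear")
  }
  h <- crossprod(a, b)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps mobile -> reference
  trans <- as.numeric(cr - rot %*% cm)
  moved <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  new_rigid_transform(rot, trans, rmsd)
}

new_rigid_transform <- function(rotation, translation, fit_rmsd = NA_real_) {
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-8,
            abs(det(rotation) - 1) < 1e-8)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 fit_rmsd = fit_rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.2f deg, |t| = %.3f A, fit_rmsd = %s\n",
              ang * 180 / pi, sqrt(sum(x$translation^2)),
              ifelse(is.na(x$fit_rmsd), "NA", sprintf("%.4f A", x$fit_rmsd))))
  invisible(x)
}

#' Identity rigid transform
#' @return a `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() new_rigid_transform(diag(3), c(0, 0, 0), 0)

#' Apply a rigid transform
#'
#' @param x a `mol_structure` or an n x 3 coordinate matrix.
#' @param tf a `rigid_transform`.
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "mol_structure")) {
    coords(x) <- apply_transform(coords(x), tf)
    return(x)
  }
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

# angle (radians) of a rotation matrix
rotation_angle <- function(r) {
  acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2)))
}

# rotation matrix about a (unit) axis by angle (radians)
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  c0 * diag(3) + s0 * ux + (1 - c0) * tcrossprod(u)
}

# seeded uniform random rotation (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b numeric n x 3 matrices in the same frame (no fitting done).
#' @return numeric RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# All atom pairs within `cutoff`, via spatial binning; returns two-column
# integer matrix (i < j).  Linear in atom count for bounded density.
close_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), 0, 2))
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  id <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  cells <- split(seq_len(n), id)
  keyu <- do.call(rbind, lapply(strsplit(names(cells), ","), as.numeric))
  out <- vector("list", length(cells))
  # neighbour cell offsets (half-shell to avoid double visits)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz >= 0), ]
  lut <- stats::setNames(seq_along(cells), names(cells))
  res <- list(); ri <- 0L
  for (ci in seq_along(cells)) {
    a_idx <- cells[[ci]]
    for (oi in seq_len(nrow(offs))) {
      nk <- keyu[ci, ] + as.numeric(offs[oi, ])
      nid <- paste(nk[1], nk[2], nk[3], sep = ",")
      cj <- lut[nid]
      if (is.na(cj)) next
      b_idx <- cells[[cj]]
      if (ci == cj) {
        if (length(a_idx) < 2) next
        cmb <- utils::combn(a_idx, 2)
        pi_ <- cmb[1, ]; pj_ <- cmb[2, ]
      } else {
        g <- expand.grid(a_idx, b_idx)
        pi_ <- g[, 1]; pj_ <- g[, 2]
      }
      d2 <- rowSums((xyz[pi_, , drop = FALSE] - xyz[pj_, , drop = FALSE])^2)
      keep <- d2 <= cutoff^2
      if (any(keep)) {
        ri <- ri + 1L
        res[[ri]] <- cbind(pmin(pi_[keep], pj_[keep]), pmax(pi_[keep], pj_[keep]))
      }
    }
  }
  if (!ri) return(matrix(integer(), 0, 2))
  out <- do.call(rbind, res)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
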