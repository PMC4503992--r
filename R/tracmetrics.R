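#' Root-mean-square traction over a cell
#'
#' RMS magnitude of the traction vectors at the grid nodes inside the cell
#' contour, in Pa.
#'
#' @param traction A [traction_field()].
#' @param mask A [cell_mask()] overlapping the grid.
#' @return Scalar, Pa.
#' @export
rms_traction <- function(traction, mask) {
  stopifnot(inherits(traction, "traction_field"))
  inm <- mask_raster(mask, traction$grid)
  if (!any(inm)) stop("empty mask on the traction grid")
  sqrt(mean(traction$tx[inm]^2 + traction$ty[inm]^2))
}

#' First-order moment matrix of the traction field
#'
#' `M_ij = 1/2 sum_in-mask (x_i t_j + x_j t_i) dA`, with positions taken
#' relative to the traction-weighted centroid of the cell.  Units pN um
#' (Pa x um^3).  The matrix is symmetric by construction; for a contractile
#' cell (tractions pointing inward) its trace is negative.
#'
#' @param traction A [traction_field()].
#' @param mask A [cell_mask()].
#' @return Symmetric 2x2 matrix, pN um.
#' @export
moment_matrix <- function(traction, mask) {
  stopifnot(inherits(traction, "traction_field"))
  grid <- traction$grid
  inm <- mask_raster(mask, grid)
  if (!any(inm)) stop("empty mask on the traction grid")
  xy <- grid_xy(grid)
  dA <- grid$spacing^2
  tx <- traction$tx[inm]; ty <- traction$ty[inm]
  x <- xy$x[inm]; y <- xy$y[inm]
  # traction-weighted centroid: weights |t|, falling back to geometric
  w <- sqrt(tx^2 + ty^2)
  if (sum(w) > 0) {
    cx <- sum(w * x) / sum(w); cy <- sum(w * y) / sum(w)
  } else {
    cx <- mean(x); cy <- mean(y)
  }
  x <- x - cx; y <- y - cy
  mxx <- sum(x * tx) * dA
  myy <- sum(y * ty) * dA
  mxy <- 0.5 * sum(x * ty + y * tx) * dA
  matrix(c(mxx, mxy, mxy, myy), 2, 2)
}

#' Net contractile moment
#'
#' Trace of the first-order moment matrix; an integrated measure of
#' traction and spreading area, negative for contractile cells.
#'
#' @param M Symmetric 2x2 moment matrix, pN um.
#' @return Scalar, pN um.
#' @export
net_contractile_moment <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 2))
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("moment matrix must be symmetric")
  M[1, 1] + M[2, 2]
}

#' Polarity ellipse of the moment matrix
#'
#' Eigen-decomposition of M: semi-axes are the absolute eigenvalues sorted
#' descending, orientation is the angle of the dominant eigenvector folded
#' to `[0, pi)` (traction axes are unsigned), and polarity is
#' `|l1| / (|l1| + |l2|)`, in `[0.5, 1]`: 0.5 for isotropic traction,
#' 1 for a pure uniaxial dipole.  This normalized form of the eigenvalue
#' ratio is used instead of the raw ratio `l1/l2`, which diverges for
#' degenerate (uniaxial) dipoles.
#'
#' @param M Symmetric, nonzero 2x2 moment matrix, pN um.
#' @return List with `semi_axes` (pN um, descending), `orientation`
#'   (radians in `[0, pi)`), `polarity`, and `eigenvalues` (signed, sorted
#'   by absolute value, descending).
#' @export
polarity_ellipse <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 2))
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("moment matrix must be symmetric")
  if (all(M == 0)) stop("zero moment matrix has no defined orientation")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  lam <- e$values[ord]
  v1 <- e$vectors[, ord[1]]
  theta <- atan2(v1[2], v1[1]) %% pi
  if (pi - theta < 1e-9) theta <- 0   # fold the pi boundary onto 0
  list(semi_axes = abs(lam),
       orientation = theta,
       polarity = abs(lam[1]) / (abs(lam[1]) + abs(lam[2])),
       eigenvalues = lam)
}

#' Per-cell traction summary
#'
#' Composes the scalar mechanics read-outs for one cell: RMS traction, net
#' force, first-order moment matrix, net contractile moment, polarity
#' ellipse, and spread area.
#'
#' @param traction A [traction_field()].
#' @param mask A [cell_mask()].
#' @return Object of class `traction_summary`: list with `rms_traction`
#'   (Pa), `net_force` (pN, 2-vector), `moment_matrix` (pN um),
#'   `net_contractile_moment` (pN um), `eigenvalues`, `orientation`,
#'   `polarity` (NA for an all-zero field), `spread_area` (um^2).
#' @export
summarize_cell <- function(traction, mask) {
  grid <- traction$grid
  inm <- mask_raster(mask, grid)
  if (!any(inm)) stop("empty mask on the traction grid")
  dA <- grid$spacing^2
  net <- c(sum(traction$tx[inm]), sum(traction$ty[inm])) * dA
  rms <- rms_traction(traction, mask)
  M <- moment_matrix(traction, mask)
  ncm <- net_contractile_moment(M)
  if (all(M == 0)) {
    pe <- list(semi_axes = c(0, 0), orientation = NA_real_,
               polarity = NA_real_, eigenvalues = c(0, 0))
  } else {
    pe <- polarity_ellipse(M)
  }
  area <- if (!is.na(mask$area)) mask$area else sum(inm) * dA
  structure(list(rms_traction = rms,
                 net_force = net,
                 moment_matrix = M,
                 net_contractile_moment = ncm,
                 eigenvalues = pe$eigenvalues,
                 orientation = pe$orientation,
                 polarity = pe$polarity,
                 spread_area = area),
            class = "traction_summary")
}

#' @export
print.traction_summary <- function(x, ...) {
  cat("Traction summary\n")
  cat(sprintf("  RMS traction        : %.4g Pa\n", x$rms_traction))
  cat(sprintf("  net force           : (%.3g, %.3g) pN\n",
              x$net_force[1], x$net_force[2]))
  cat(sprintf("  contractile moment  : %.4g pN um\n", x$net_contractile_moment))
  cat(sprintf("  polarity            : %s\n",
              ifelse(is.na(x$polarity), "undefined (zero field)",
                     sprintf("%.3f", x$polarity))))
  cat(sprintf("  orientation         : %s rad\n",
              ifelse(is.na(x$orientation), "undefined",
                     sprintf("%.3f", x$orientation))))
  cat(sprintf("  spread area         : %.4g um^2\n", x$spread_area))
  invisible(x)
}
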