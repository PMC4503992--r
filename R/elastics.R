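#' Elastic gel substrate
#'
#' Mechanical description of the polyacrylamide half-space the cells pull on.
#' Typical experiments use gels of 1, 11 or 26 kPa Young's modulus; the
#' Poisson ratio defaults to the incompressible limit 0.5, the standard
#' assumption for polyacrylamide traction substrates.
#'
#' @param youngs_modulus Young's modulus in Pa (> 0).
#' @param poisson_ratio Poisson ratio, in (0, 0.5].
#' @return An object of class `gel_substrate`.
#' @export
#' @examples
#' gel_substrate(11e3)
gel_substrate <- function(youngs_modulus, poisson_ratio = 0.5) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1,
            is.finite(youngs_modulus))
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0")
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1 ||
      poisson_ratio <= 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must lie in (0, 0.5]")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "gel_substrate")
}

#' Regular grid specification
#'
#' Square-spaced node grid in the substrate plane.  Coordinates are in
#' micrometres with the origin at the lower-left node, x increasing to the
#' right (columns) and y increasing upwards (rows).
#'
#' @param spacing Node spacing in um (> 0).
#' @param shape Integer vector `(ny, nx)`, both >= 2.
#' @param origin Coordinates of the first node, um.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing, shape, origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar")
  if (length(shape) != 2 || any(shape < 2))
    stop("shape must be (ny, nx) with both >= 2")
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  structure(list(spacing = spacing, shape = shape,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

# node coordinate axes of a grid_spec
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[2]) - 1) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$shape[1]) - 1) * grid$spacing)
}

# full coordinate matrices (ny x nx)
grid_xy <- function(grid) {
  ax <- grid_axes(grid)
  list(x = matrix(ax$x, grid$shape[1], grid$shape[2], byrow = TRUE),
       y = matrix(ax$y, grid$shape[1], grid$shape[2]))
}

new_vector_field <- function(grid, vx, vy, class, names2) {
  stopifnot(inherits(grid, "grid_spec"))
  vx <- as.matrix(vx); vy <- as.matrix(vy)
  if (!all(dim(vx) == grid$shape) || !all(dim(vy) == grid$shape))
    stop("field dimensions must match grid shape (ny, nx)")
  if (!all(is.finite(vx)) || !all(is.finite(vy)))
    stop("field values must be finite")
  out <- list(grid = grid)
  out[[names2[1]]] <- vx
  out[[names2[2]]] <- vy
  structure(out, class = class)
}

#' Substrate displacement field
#'
#' Gridded 2-D bead displacement vectors in um.
#'
#' @param grid A [grid_spec()].
#' @param ux,uy Matrices `(ny, nx)` of x/y displacement components, um.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(grid, ux, uy)
  new_vector_field(grid, ux, uy, "displacement_field", c("ux", "uy"))

#' Traction field
#'
#' Gridded 2-D traction stress vectors in Pa on the same node grid as the
#' displacements.  With coordinates in um, 1 Pa x um^2 = 1 pN, so integrals
#' of traction over area are reported in pN.
#'
#' @param grid A [grid_spec()].
#' @param tx,ty Matrices `(ny, nx)` of traction components, Pa.
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(grid, tx, ty)
  new_vector_field(grid, tx, ty, "traction_field", c("tx", "ty"))

#' Cell contour mask
#'
#' The traced outline of a cell, as a simple polygon in um and/or a logical
#' raster aligned to a node grid.  The polygon is closed implicitly (last
#' vertex connects to the first).
#'
#' @param polygon Two-column matrix of vertex coordinates (um), or NULL.
#' @param grid Optional [grid_spec()] used to rasterize the polygon.
#' @param raster Optional logical matrix `(ny, nx)`; computed from the
#'   polygon when a grid is given.
#' @return Object of class `cell_mask` with elements `polygon`, `raster`,
#'   `grid`, `area` (um^2, polygon area when available, else raster area).
#' @export
cell_mask <- function(polygon = NULL, grid = NULL, raster = NULL) {
  if (is.null(polygon) && is.null(raster))
    stop("either a polygon or a raster is required")
  area <- NA_real_
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3)
      stop("polygon must be an n x 2 matrix with n >= 3")
    if (polygon_self_intersects(polygon))
      stop("polygon must be simple (non-self-intersecting)")
    area <- abs(polygon_signed_area(polygon))
    if (area <= 0) stop("polygon area must be > 0")
    if (!is.null(grid) && is.null(raster))
      raster <- rasterize_polygon(polygon, grid)
  }
  if (!is.null(raster)) {
    raster <- as.matrix(raster)
    storage.mode(raster) <- "logical"
    if (!is.null(grid)) {
      if (!all(dim(raster) == grid$shape))
        stop("raster dimensions must match grid shape")
      if (is.na(area)) area <- sum(raster) * grid$spacing^2
    }
  }
  structure(list(polygon = polygon, raster = raster, grid = grid,
                 area = area),
            class = "cell_mask")
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# brute-force segment pair test; contours have few vertices
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# even-odd rule point-in-polygon, vectorized over grid nodes
rasterize_polygon <- function(polygon, grid) {
  xy <- grid_xy(grid)
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- matrix(FALSE, grid$shape[1], grid$shape[2])
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > xy$y) != (py[j] > xy$y))
    xint <- (px[j] - px[i]) * (xy$y - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, crosses & (xy$x < xint))
    j <- i
  }
  inside
}

# logical raster for a mask on a given grid
mask_raster <- function(mask, grid) {
  stopifnot(inherits(mask, "cell_mask"))
  if (!is.null(mask$raster) && !is.null(mask$grid) &&
      identical(mask$grid$shape, grid$shape) &&
      isTRUE(all.equal(mask$grid$spacing, grid$spacing)) &&
      isTRUE(all.equal(mask$grid$origin, grid$origin)))
    return(mask$raster)
  if (is.null(mask$polygon))
    stop("mask has no polygon and its raster is on a different grid")
  rasterize_polygon(mask$polygon, grid)
}

#' Boussinesq surface Green's tensor
#'
#' In-plane surface displacement response of a semi-infinite elastic solid
#' to a tangential point force applied at the origin of its free surface:
#' `G_ij(r) = (1 + nu) / (pi E |r|) * ((1 - nu) delta_ij + nu r_i r_j / |r|^2)`.
#' With E in Pa and r in um, G has units of um per (Pa um^2) = um/pN.
#'
#' @param r 2-vector offset in um; `|r| > 0`.
#' @param gel A [gel_substrate()].
#' @return Symmetric 2x2 matrix.
#' @export
#' @examples
#' boussinesq_greens_tensor(c(10, 0), gel_substrate(1000))[1, 1] # 4.77e-5
boussinesq_greens_tensor <- function(r, gel) {
  stopifnot(inherits(gel, "gel_substrate"), length(r) == 2, all(is.finite(r)))
  rn <- sqrt(sum(r^2))
  if (rn == 0)
    stop("Green's tensor is singular at r = 0; the grid quadrature handles it")
  E <- gel$youngs_modulus; nu <- gel$poisson_ratio
  pref <- (1 + nu) / (pi * E * rn)
  pref * ((1 - nu) * diag(2) + nu * tcrossprod(r) / rn^2)
}

# Discrete Green's kernel on the zero-padded grid, wrapped coordinates.
# The singular self-cell uses the analytic cell average of G over one grid
# square: integral of 1/r over a square of side h is 4 h ln(1 + sqrt(2)),
# and integral of x^2/r^3 is half of that by symmetry.
greens_kernel <- function(grid, gel, pad_shape) {
  h <- grid$spacing
  E <- gel$youngs_modulus; nu <- gel$poisson_ratio
  py <- pad_shape[1]; px <- pad_shape[2]
  ix <- seq_len(px) - 1; iy <- seq_len(py) - 1
  dx <- ifelse(ix > px / 2, ix - px, ix) * h
  dy <- ifelse(iy > py / 2, iy - py, iy) * h
  X <- matrix(dx, py, px, byrow = TRUE)
  Y <- matrix(dy, py, px)
  R <- sqrt(X^2 + Y^2)
  pref <- (1 + nu) / (pi * E)
  Rs <- R; Rs[1, 1] <- 1   # placeholder, overwritten below
  gxx <- pref * ((1 - nu) / Rs + nu * X^2 / Rs^3)
  gyy <- pref * ((1 - nu) / Rs + nu * Y^2 / Rs^3)
  gxy <- pref * nu * X * Y / Rs^3
  c_avg <- 4 * log(1 + sqrt(2)) / h   # cell-average of 1/r times h^2 -> 1/h
  self <- pref * c_avg * ((1 - nu) + nu / 2)
  gxx[1, 1] <- self; gyy[1, 1] <- self; gxy[1, 1] <- 0
  list(gxx = gxx, gxy = gxy, gyy = gyy)
}

pad_shape_for <- function(grid, factor = 2) as.integer(grid$shape * factor)

embed_pad <- function(m, pad_shape) {
  out <- matrix(0, pad_shape[1], pad_shape[2])
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) Re(stats::fft(m, inverse = TRUE)) / length(m)

#' Forward elastic solution (traction to displacement)
#'
#' Computes the surface displacement produced by a traction field on an
#' elastic half-space, as the discrete convolution of the Boussinesq
#' Green's tensor with `t * dA`, evaluated in Fourier space with >= 2x
#' zero-padding per axis (linear, not circular, convolution).
#'
#' @param traction A [traction_field()].
#' @param gel A [gel_substrate()].
#' @return A [displacement_field()] on the same grid, um.
#' @export
forward_solve <- function(traction, gel) {
  stopifnot(inherits(traction, "traction_field"), inherits(gel, "gel_substrate"))
  if (anyNA(traction$tx) || anyNA(traction$ty))
    stop("traction contains NaN")
  grid <- traction$grid
  ps <- pad_shape_for(grid)
  ker <- greens_kernel(grid, gel, ps)
  dA <- grid$spacing^2
  tx <- fft2(embed_pad(traction$tx, ps))
  ty <- fft2(embed_pad(traction$ty, ps))
  Gxx <- fft2(ker$gxx); Gxy <- fft2(ker$gxy); Gyy <- fft2(ker$gyy)
  ux <- ifft2(Gxx * tx + Gxy * ty) * dA
  uy <- ifft2(Gxy * tx + Gyy * ty) * dA
  ny <- grid$shape[1]; nx <- grid$shape[2]
  displacement_field(grid, ux[seq_len(ny), seq_len(nx)],
                     uy[seq_len(ny), seq_len(nx)])
}

# Per-grid discrete elastic operator in Fourier space.  The forward map
# from grid tractions to grid displacements is crop o conv(G) o zero-pad;
# its per-frequency symbol on the padded grid is the real symmetric 2x2
# block [[a, b], [b, c]] (kernel is real and even, so its DFT is real).
# Returns closures for the operator (self-adjoint under the even kernel),
# the direct Tikhonov filter, and the largest symbol singular value.
tfm_operator <- function(grid, gel) {
  ps <- pad_shape_for(grid)
  ker <- greens_kernel(grid, gel, ps)
  dA <- grid$spacing^2
  a <- Re(fft2(ker$gxx)) * dA
  b <- Re(fft2(ker$gxy)) * dA
  cc <- Re(fft2(ker$gyy)) * dA
  disc <- sqrt(((a - cc) / 2)^2 + b^2)
  smax <- max(abs((a + cc) / 2) + disc)
  ny <- grid$shape[1]; nx <- grid$shape[2]
  crop <- function(m) m[seq_len(ny), seq_len(nx)]
  apply_op <- function(tx, ty) {
    fx <- fft2(embed_pad(tx, ps)); fy <- fft2(embed_pad(ty, ps))
    list(x = crop(ifft2(a * fx + b * fy)),
         y = crop(ifft2(b * fx + cc * fy)))
  }
  # direct filter t = (A^2 + alpha2)^-1 A u (also the CG preconditioner
  # without the leading A when `plain = TRUE`)
  filter_op <- function(ux, uy, alpha2, plain = FALSE) {
    fx <- fft2(embed_pad(ux, ps)); fy <- fft2(embed_pad(uy, ps))
    m11 <- a^2 + b^2 + alpha2
    m22 <- cc^2 + b^2 + alpha2
    m12 <- b * (a + cc)
    if (plain) { r1 <- fx; r2 <- fy }
    else { r1 <- a * fx + b * fy; r2 <- b * fx + cc * fy }
    det <- m11 * m22 - m12^2
    list(x = crop(ifft2((m22 * r1 - m12 * r2) / det)),
         y = crop(ifft2((m11 * r2 - m12 * r1) / det)))
  }
  list(apply = apply_op, filter = filter_op, smax = smax)
}

# Masked Tikhonov inversion by preconditioned conjugate gradients on the
# normal equations  (P F' F P + alpha2 I) t = P F' u,  P = mask projector,
# preconditioned by the circulant filter (F'F + alpha2)^-1.  Stops when the
# relative displacement misfit changes by less than tol between sweeps.
tikhonov_cg <- function(displacement, gel, alpha2, inm = NULL,
                        tol = 1e-8, max_iter = 100) {
  grid <- displacement$grid
  op <- tfm_operator(grid, gel)
  ux <- displacement$ux; uy <- displacement$uy
  u_norm <- field_l2(ux, uy)
  proj <- function(v) if (is.null(inm)) v else list(x = v$x * inm, y = v$y * inm)
  hess <- function(v) {
    fv <- op$apply(v$x, v$y)
    ftf <- op$apply(fv$x, fv$y)        # F'F via even-kernel self-adjointness
    proj(list(x = ftf$x + alpha2 * v$x, y = ftf$y + alpha2 * v$y))
  }
  rhs <- proj(op$apply(ux, uy))
  x <- proj(op$filter(ux, uy, alpha2))
  misfit_of <- function(v) {
    fv <- op$apply(v$x, v$y)
    if (u_norm > 0) field_l2(fv$x - ux, fv$y - uy) / u_norm else 0
  }
  dot <- function(p, q) sum(p$x * q$x + p$y * q$y)
  r <- hess(x)
  r <- list(x = rhs$x - r$x, y = rhs$y - r$y)
  z <- proj(op$filter(r$x, r$y, alpha2, plain = TRUE))
  p <- z
  rz <- dot(r, z)
  misfit_prev <- misfit_of(x)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    hp <- hess(p)
    php <- dot(p, hp)
    if (php <= 0) { converged <- TRUE; break }
    alpha <- rz / php
    x <- list(x = x$x + alpha * p$x, y = x$y + alpha * p$y)
    r <- list(x = r$x - alpha * hp$x, y = r$y - alpha * hp$y)
    misfit <- misfit_of(x)
    if (abs(misfit_prev - misfit) <
        tol * max(misfit_prev, .Machine$double.eps)) {
      misfit_prev <- misfit
      converged <- TRUE
      break
    }
    misfit_prev <- misfit
    z <- proj(op$filter(r$x, r$y, alpha2, plain = TRUE))
    rz_new <- dot(r, z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- list(x = z$x + beta * p$x, y = z$y + beta * p$y)
  }
  out <- traction_field(grid, x$x, x$y)
  attr(out, "misfit") <- misfit_prev
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Fourier-transform traction cytometry (unconstrained inverse)
#'
#' Recovers tractions from a gridded displacement field by solving the
#' Fourier-space deconvolution of the discrete Boussinesq kernel with a
#' zeroth-order Tikhonov penalty: `min ||F t - u||^2 + alpha^2 ||t||^2`,
#' where F is the (zero-padded, linear-convolution) forward operator.
#' `reg_lambda` is dimensionless: `alpha = reg_lambda * s` with `s` the
#' largest kernel singular value, so `reg_lambda = 0` is the plain
#' unregularized inverse and large values drive the solution to zero.
#' The system is solved by conjugate gradients preconditioned with the
#' circulant Tikhonov filter (which is also the starting iterate); the
#' returned traction is real-valued.
#'
#' @param displacement A [displacement_field()].
#' @param gel A [gel_substrate()].
#' @param reg_lambda Dimensionless regularization weight, >= 0.
#' @param tol Relative misfit-change stopping tolerance.
#' @param max_iter Maximum CG iterations.
#' @return A [traction_field()], Pa, with attributes `misfit`,
#'   `iterations`, `converged`.
#' @export
fttc_inverse <- function(displacement, gel, reg_lambda = 0, tol = 1e-8,
                         max_iter = 100) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(gel, "gel_substrate"))
  if (!is.numeric(reg_lambda) || length(reg_lambda) != 1 || reg_lambda < 0)
    stop("reg_lambda must be a scalar >= 0")
  grid <- displacement$grid
  if (any(grid$shape < 8))
    stop("grid too small for Fourier inversion (need >= 8 nodes per axis)")
  op_smax <- tfm_operator(grid, gel)$smax
  tikhonov_cg(displacement, gel, (reg_lambda * op_smax)^2,
              inm = NULL, tol = tol, max_iter = max_iter)
}

field_l2 <- function(fx, fy) sqrt(sum(fx^2 + fy^2))

#' Relative L2 difference between two traction or displacement fields
#'
#' @param f,g Fields of the same class on the same grid.
#' @return `||f - g||_2 / ||g||_2` over both components.
#' @export
relative_l2 <- function(f, g) {
  n2 <- function(fl) if (inherits(fl, "traction_field")) list(fl$tx, fl$ty)
                     else list(fl$ux, fl$uy)
  a <- n2(f); b <- n2(g)
  field_l2(a[[1]] - b[[1]], a[[2]] - b[[2]]) / field_l2(b[[1]], b[[2]])
}

#' L-curve choice of the regularization weight
#'
#' Evaluates the Tikhonov inverse on a logarithmic grid of `n_lambda`
#' values and returns the lambda at the L-curve corner, located as the
#' point of maximum Menger curvature of the (log residual norm,
#' log solution norm) curve.
#'
#' @param displacement A [displacement_field()].
#' @param gel A [gel_substrate()].
#' @param lambda_range Length-2 range of dimensionless lambdas searched.
#' @param n_lambda Number of grid points (default 20).
#' @return List with `lambda`, and the searched `lambdas`, `residual_norms`,
#'   `solution_norms`.
#' @export
select_lambda_lcurve <- function(displacement, gel,
                                 lambda_range = c(1e-4, 1), n_lambda = 20) {
  grid <- displacement$grid
  op <- tfm_operator(grid, gel)
  lams <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                  length.out = n_lambda))
  rho <- eta <- numeric(n_lambda)
  for (i in seq_along(lams)) {
    # direct circulant Tikhonov filter: its norms trace the classic L shape
    t_i <- op$filter(displacement$ux, displacement$uy,
                     (lams[i] * op$smax)^2)
    u_i <- op$apply(t_i$x, t_i$y)
    rho[i] <- field_l2(u_i$x - displacement$ux, u_i$y - displacement$uy)
    eta[i] <- field_l2(t_i$x, t_i$y)
  }
  x <- log(pmax(rho, .Machine$double.xmin))
  y <- log(pmax(eta, .Machine$double.xmin))
  curv <- rep(NA_real_, n_lambda)
  for (i in 2:(n_lambda - 1)) {
    ax <- x[i - 1]; ay <- y[i - 1]; bx <- x[i]; by <- y[i]
    cx <- x[i + 1]; cy <- y[i + 1]
    area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
    d <- sqrt((bx - ax)^2 + (by - ay)^2) * sqrt((cx - bx)^2 + (cy - by)^2) *
      sqrt((cx - ax)^2 + (cy - ay)^2)
    curv[i] <- if (d > 0) 2 * area2 / d else 0
  }
  best <- which.max(curv)
  list(lambda = lams[best], lambdas = lams,
       residual_norms = rho, solution_norms = eta)
}

#' Cell-contour constrained traction inversion
#'
#' Constrained traction microscopy: tractions are forced to exactly zero
#' outside the traced cell contour.  The in-mask solution minimizes the
#' displacement misfit plus the Tikhonov penalty over tractions supported
#' inside the mask, via the same filter-preconditioned conjugate-gradient
#' iteration as [fttc_inverse()] with a mask projection applied each sweep
#' (iteratively: invert, zero outside the mask, forward-correct the
#' residual).  Stops when the relative misfit change drops below `tol` or
#' after `max_iter` sweeps.  With a mask covering the whole grid this is
#' identical to [fttc_inverse()].
#'
#' @param displacement A [displacement_field()].
#' @param mask A [cell_mask()] overlapping the grid.
#' @param gel A [gel_substrate()].
#' @param reg_lambda Dimensionless Tikhonov weight (see [fttc_inverse()]).
#' @param tol Relative misfit-change stopping tolerance.
#' @param max_iter Maximum sweeps.
#' @return A [traction_field()], exactly zero outside the mask, with
#'   attributes `misfit` (achieved relative displacement misfit),
#'   `iterations`, and `converged` (FALSE triggers a warning but the field
#'   is still returned).
#' @export
constrained_inverse <- function(displacement, mask, gel, reg_lambda = 0,
                                tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(displacement, "displacement_field"),
            inherits(mask, "cell_mask"),
            inherits(gel, "gel_substrate"))
  grid <- displacement$grid
  if (any(grid$shape < 8))
    stop("grid too small for Fourier inversion (need >= 8 nodes per axis)")
  inm <- mask_raster(mask, grid)
  if (!any(inm)) stop("mask does not overlap the displacement grid")
  op_smax <- tfm_operator(grid, gel)$smax
  out <- tikhonov_cg(displacement, gel, (reg_lambda * op_smax)^2,
                     inm = if (all(inm)) NULL else inm,
                     tol = tol, max_iter = max_iter)
  if (!all(inm)) {  # exact zeros outside the contour, by definition
    out$tx[!inm] <- 0
    out$ty[!inm] <- 0
  }
  if (!attr(out, "converged"))
    warning(sprintf(
      "constrained inversion did not converge in %d iterations (misfit %.3g)",
      attr(out, "iterations"), attr(out, "misfit")))
  out
}

#' Interpolate scattered bead displacements onto a grid
#'
#' Bead tracking yields displacements at scattered positions; the Fourier
#' inversion needs them on a regular grid.  Each grid node takes the value
#' of a local plane (weighted linear least squares) fitted through its
#' `k` nearest beads; nodes whose nearest bead is farther than
#' `max_gap` grid spacings are outside the sampled region and set to 0.
#'
#' @param points Data frame with columns `x_um`, `y_um`, `ux_um`, `uy_um`.
#' @param grid A [grid_spec()].
#' @param k Number of neighbours per node (>= 3).
#' @param max_gap Nearest-bead cutoff in units of grid spacing.
#' @return A [displacement_field()].
#' @export
interp_displacements <- function(points, grid, k = 8, max_gap = 3) {
  req <- c("x_um", "y_um", "ux_um", "uy_um")
  if (!all(req %in% names(points))) stop("points must have columns ", paste(req, collapse = ", "))
  if (nrow(points) < 3) stop("need at least 3 scattered points")
  k <- min(k, nrow(points))
  xy <- grid_xy(grid)
  ux <- uy <- matrix(0, grid$shape[1], grid$shape[2])
  px <- points$x_um; py <- points$y_um
  for (i in seq_along(xy$x)) {
    d2 <- (px - xy$x[[i]])^2 + (py - xy$y[[i]])^2
    ord <- order(d2)[seq_len(k)]
    if (sqrt(d2[ord[1]]) > max_gap * grid$spacing) next
    w <- 1 / (d2[ord] + (0.5 * grid$spacing)^2)
    X <- cbind(1, px[ord] - xy$x[[i]], py[ord] - xy$y[[i]])
    XtW <- t(X * w)
    coef <- tryCatch(solve(XtW %*% X, XtW %*% cbind(points$ux_um[ord],
                                                    points$uy_um[ord])),
                     error = function(e) NULL)
    if (is.null(coef)) {
      ux[i] <- sum(w * points$ux_um[ord]) / sum(w)
      uy[i] <- sum(w * points$uy_um[ord]) / sum(w)
    } else {
      ux[i] <- coef[1, 1]; uy[i] <- coef[1, 2]
    }
  }
  displacement_field(grid, ux, uy)
}
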