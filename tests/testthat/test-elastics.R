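test_that("Boussinesq Green's tensor matches its closed form", {
  gel <- gel_substrate(1000, 0.5)
  G <- boussinesq_greens_tensor(c(10, 0), gel)
  expect_equal(G[1, 1], 1.5 / (pi * 1000 * 10), tolerance = 1e-12)
  expect_equal(G[1, 2], 0)
  # on the y-axis only the (1 - nu) term contributes to G_xx
  Gy <- boussinesq_greens_tensor(c(0, 10), gel)
  expect_equal(Gy[1, 1], 0.75 / (pi * 1000 * 10), tolerance = 1e-12)
  # even symmetry and matrix symmetry at arbitrary offsets
  for (r in list(c(3, 4), c(-7, 2), c(1.5, -9))) {
    Ga <- boussinesq_greens_tensor(r, gel)
    expect_equal(Ga, boussinesq_greens_tensor(-r, gel))
    expect_equal(Ga, t(Ga))
  }
  expect_error(boussinesq_greens_tensor(c(0, 0), gel), "singular")
})

test_that("forward solution is linear and reproduces the point-force limit", {
  gel <- gel_substrate(1000, 0.5)
  grid <- grid_spec(2, c(64, 64))
  z <- matrix(0, 64, 64)
  expect_equal(forward_solve(traction_field(grid, z, z), gel)$ux, z)
  set.seed(4)
  t1 <- traction_field(grid, matrix(rnorm(64^2), 64), matrix(rnorm(64^2), 64))
  t2 <- traction_field(grid, matrix(rnorm(64^2), 64), matrix(rnorm(64^2), 64))
  u1 <- forward_solve(t1, gel); u2 <- forward_solve(t2, gel)
  u12 <- forward_solve(traction_field(grid, t1$tx + t2$tx, t1$ty + t2$ty), gel)
  expect_equal(u12$ux, u1$ux + u2$ux, tolerance = 1e-10)
  expect_equal(u12$uy, u1$uy + u2$uy, tolerance = 1e-10)
  # isolated 100 pN x-force at a node: u_x ten microns away approaches the
  # closed-form point-force value G_xx * F = 4.77e-3 um
  tx <- z; tx[33, 33] <- 100 / grid$spacing^2
  u <- forward_solve(traction_field(grid, tx, z), gel)
  expect_equal(u$ux[33, 38], 1.5 * 100 / (pi * 1000 * 10), tolerance = 0.02)
  expect_error(forward_solve(traction_field(grid, tx, z + NA), gel))
})

test_that("scaling laws: displacement is linear in traction, inverse in E", {
  sc <- make_dipole_scene(n = 32)
  gel2 <- gel_substrate(2000, 0.5)
  u_half <- forward_solve(sc$traction, gel2)
  expect_equal(u_half$ux, sc$displacement$ux / 2, tolerance = 1e-12)
  t2 <- traction_field(sc$grid, 2 * sc$traction$tx, 2 * sc$traction$ty)
  expect_equal(forward_solve(t2, sc$gel)$uy, 2 * sc$displacement$uy,
               tolerance = 1e-12)
})

test_that("unconstrained inversion round-trips a noiseless dipole scene", {
  sc <- make_dipole_scene()
  t_hat <- fttc_inverse(sc$displacement, sc$gel, 0)
  expect_lt(relative_l2(t_hat, sc$traction), 0.01)
  # heavy regularization drives the solution toward zero
  t_big <- fttc_inverse(sc$displacement, sc$gel, 1e4)
  expect_lt(max(abs(t_big$tx)), 1e-6 * max(abs(sc$traction$tx)))
  expect_error(fttc_inverse(
    displacement_field(grid_spec(2, c(4, 4)), matrix(0, 4, 4),
                       matrix(0, 4, 4)), sc$gel), "too small")
  expect_error(fttc_inverse(sc$displacement, sc$gel, -1), "reg_lambda")
})

test_that("rotating a scene by 90 degrees rotates forward and inverse", {
  gel <- gel_substrate(5000, 0.5)
  grid <- grid_spec(2, c(16, 16))
  set.seed(11)
  base <- matrix(0, 16, 16)
  tx <- base; ty <- base
  tx[6:8, 9:11] <- 40; ty[10:12, 5:6] <- -25   # arbitrary asymmetric field
  tr <- traction_field(grid, tx, ty)
  u <- forward_solve(tr, gel)
  rot_t <- rot90_field(tx, ty)
  u_rot <- forward_solve(traction_field(grid, rot_t$x, rot_t$y), gel)
  u_expect <- rot90_field(u$ux, u$uy)
  expect_equal(u_rot$ux, u_expect$x, tolerance = 1e-10)
  expect_equal(u_rot$uy, u_expect$y, tolerance = 1e-10)
  t_hat <- fttc_inverse(u, gel, 1e-4)
  t_hat_rot <- fttc_inverse(displacement_field(grid, u_rot$ux, u_rot$uy),
                            gel, 1e-4)
  t_expect <- rot90_field(t_hat$tx, t_hat$ty)
  expect_equal(t_hat_rot$tx, t_expect$x, tolerance = 1e-6)
  expect_equal(t_hat_rot$ty, t_expect$y, tolerance = 1e-6)
})

test_that("constrained inversion honors the contour exactly and recovers", {
  sc <- make_dipole_scene()
  t_c <- constrained_inverse(sc$displacement, sc$mask, sc$gel, 0)
  inm <- cytomech:::mask_raster(sc$mask, sc$grid)
  expect_true(all(t_c$tx[!inm] == 0))
  expect_true(all(t_c$ty[!inm] == 0))
  expect_lt(relative_l2(t_c, sc$traction), 0.05)
  # inactive constraint: full-grid mask equals the unconstrained inverse
  full <- cell_mask(raster = matrix(TRUE, 64, 64), grid = sc$grid)
  t_full <- constrained_inverse(sc$displacement, full, sc$gel, 1e-3)
  t_unc <- fttc_inverse(sc$displacement, sc$gel, 1e-3)
  expect_lt(max(abs(t_full$tx - t_unc$tx)), 1e-8)
  expect_error(constrained_inverse(
    sc$displacement,
    cell_mask(raster = matrix(FALSE, 64, 64), grid = sc$grid), sc$gel),
    "overlap")
})

test_that("L-curve regularization beats no regularization under noise", {
  sc0 <- make_dipole_scene()
  u_rms <- sqrt(mean(sc0$displacement$ux^2 + sc0$displacement$uy^2))
  scn <- make_dipole_scene(noise_sd = 0.05 * u_rms, seed = 11)
  sel <- select_lambda_lcurve(scn$displacement, scn$gel)
  err0 <- relative_l2(constrained_inverse(scn$displacement, scn$mask,
                                          scn$gel, 0), sc0$traction)
  errL <- relative_l2(constrained_inverse(scn$displacement, scn$mask,
                                          scn$gel, sel$lambda), sc0$traction)
  expect_lt(errL, err0)
  expect_lt(errL, 0.15)
})

test_that("scattered bead displacements interpolate onto the grid", {
  grid <- grid_spec(2, c(16, 16))
  set.seed(3)
  # beads sampled from a smooth (linear) displacement field
  pts <- data.frame(x_um = runif(120, 0, 30), y_um = runif(120, 0, 30))
  pts$ux_um <- 0.01 * pts$x_um + 0.002 * pts$y_um
  pts$uy_um <- -0.004 * pts$x_um
  u <- interp_displacements(pts, grid)
  xy <- cytomech:::grid_xy(grid)
  interior <- xy$x > 4 & xy$x < 26 & xy$y > 4 & xy$y < 26
  expect_equal(u$ux[interior],
               (0.01 * xy$x + 0.002 * xy$y)[interior], tolerance = 1e-6)
  expect_equal(u$uy[interior], (-0.004 * xy$x)[interior], tolerance = 1e-6)
  expect_error(interp_displacements(pts[, 1:2], grid), "columns")
})

test_that("cell masks validate their polygons", {
  expect_error(cell_mask(polygon = rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "simple")
  m <- cell_mask(polygon = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(m$area, 100)
  grid <- grid_spec(1, c(12, 12))
  ras <- cytomech:::mask_raster(m, grid)
  xy <- cytomech:::grid_xy(grid)
  strict_in <- xy$x > 0 & xy$x < 10 & xy$y > 0 & xy$y < 10
  strict_out <- xy$x > 10 | xy$y > 10
  expect_true(all(ras[strict_in]))        # interior nodes always inside
  expect_true(!any(ras[strict_out]))      # exterior nodes never inside
})
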