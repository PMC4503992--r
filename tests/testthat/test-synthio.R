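test_that("traction scenes are forward-consistent with zero net force", {
  sc <- make_dipole_scene()
  # noiseless displacement is exactly the forward solution of the truth
  u <- forward_solve(sc$traction, sc$gel)
  expect_equal(sc$displacement$ux, u$ux)
  expect_equal(sc$displacement$uy, u$uy)
  # net force < 1e-9 of the total absolute traction integral
  dA <- sc$grid$spacing^2
  net <- sqrt(sum(sc$traction$tx)^2 + sum(sc$traction$ty)^2) * dA
  tot <- sum(sqrt(sc$traction$tx^2 + sc$traction$ty^2)) * dA
  expect_lt(net / tot, 1e-9)
  # inverse consistency (patch_radius = 2 grid spacings)
  expect_lt(relative_l2(fttc_inverse(sc$displacement, sc$gel, 0),
                        sc$traction), 0.05)
})

test_that("scene ground truth reproduces the hand-computed dipole moment", {
  # 100 pN poles separated by 20 um: trace(M) = -2000 pN um by direct sum
  sc <- make_dipole_scene(patch = 0.5)   # tight patches on grid nodes
  g <- sc$grid
  xy <- cytomech:::grid_xy(g)
  dA <- g$spacing^2
  trace_direct <- sum(xy$x * sc$traction$tx + xy$y * sc$traction$ty) * dA
  expect_equal(trace_direct, -2000, tolerance = 1e-6)
  M <- moment_matrix(sc$traction, sc$mask)
  expect_equal(M[1, 1] + M[2, 2], -2000, tolerance = 1e-4)
})

test_that("degenerate and invalid scenes are handled", {
  gel <- gel_substrate(1000)
  grid <- grid_spec(2, c(16, 16))
  sc <- simulate_traction_scene(list(), gel, grid)
  expect_true(all(sc$traction$tx == 0) && all(sc$displacement$ux == 0))
  out <- dipole_spec(c(100, 15), 0, 100, 20, 2)   # pole past the grid edge
  expect_error(simulate_traction_scene(list(out), gel, grid), "outside")
  dip <- dipole_spec(c(15, 15), 0, 100, 10, 2)
  expect_error(simulate_traction_scene(list(dip), gel, grid, noise_sd = -1),
               "noise_sd")
  expect_error(dipole_spec(c(0, 0), 0, 100, -5, 2), "separation")
})

test_that("generators are bit-identical under identical seeds", {
  sc1 <- make_dipole_scene(noise_sd = 0.01, seed = 5)
  sc2 <- make_dipole_scene(noise_sd = 0.01, seed = 5)
  expect_identical(sc1$displacement, sc2$displacement)
  expect_identical(simulate_mt_traces(10, seed = 3),
                   simulate_mt_traces(10, seed = 3))
  expect_identical(simulate_cohort(40, 2, 0.3, seed = 9),
                   simulate_cohort(40, 2, 0.3, seed = 9))
  s1 <- simulate_confocal_stack(shape = c(16, 24, 24), nucleus_radius = 3,
                                noise_sd = 2, seed = 4)
  s2 <- simulate_confocal_stack(shape = c(16, 24, 24), nucleus_radius = 3,
                                noise_sd = 2, seed = 4)
  expect_identical(s1$raw, s2$raw)
  expect_identical(simulate_intensity_table(seed = 2),
                   simulate_intensity_table(seed = 2))
})

test_that("microtubule trace generator matches its stated model", {
  tr0 <- simulate_mt_traces(5, dynamicity = 0, seed = 1)
  expect_true(all(vapply(tr0, function(t)
    suppressWarnings(max_length_change(t)) == 0, logical(1))))
  # 10 frames at 3 s: first-to-last span is 27 s inside the 30 s window
  tr <- simulate_mt_traces(3, n_frames = 10, frame_interval = 3, seed = 2)
  expect_equal(length(tr[[1]]$lengths), 10)
  expect_equal((length(tr[[1]]$lengths) - 1) * tr[[1]]$frame_interval, 27)
  expect_true(all(vapply(tr, function(t) all(t$lengths > 0), logical(1))))
  # dynamicity orders the cohort medians of max length change
  set.seed(10)
  lo <- simulate_mt_traces(40, dynamicity = 0.02, seed = NULL)
  hi <- simulate_mt_traces(40, dynamicity = 0.15, seed = NULL)
  cmp <- mt_group_comparison(lo, hi)
  expect_lt(cmp$medians["a"], cmp$medians["b"])
  expect_error(simulate_mt_traces(5, n_frames = 1), "n_frames")
})

test_that("confocal stack generator honors its ground truth contract", {
  flat <- simulate_confocal_stack(shape = c(28, 36, 36), nucleus_radius = 3,
                                  perinuclear_enrichment = 1, noise_sd = 0)
  m <- shell_and_cytoplasm_means(flat$raw, flat$masks)
  expect_equal(m$shell_over_cytoplasm, 1)
  enr <- simulate_confocal_stack(shape = c(28, 36, 36), nucleus_radius = 3,
                                 perinuclear_enrichment = 2, noise_sd = 0)
  m2 <- shell_and_cytoplasm_means(enr$raw, enr$masks)
  expect_equal(m2$shell_over_cytoplasm, 2)
  # emitted calibration triplets recover a nontrivial gain curve exactly
  g <- simulate_confocal_stack(shape = c(28, 36, 36), nucleus_radius = 3,
                               gain_coeffs = c(10, 0.5, 0.001), noise_sd = 0)
  fit <- fit_gain_curve(g$calibration[c(1, 5, 9), ])
  expect_equal(fit$a0, 10, tolerance = 1e-9)
  expect_equal(fit$a1, 0.5, tolerance = 1e-9)
  expect_equal(fit$a2, 0.001, tolerance = 1e-9)
  expect_error(simulate_confocal_stack(shape = c(28, 36, 36),
                                       nucleus_radius = 4,
                                       gain_coeffs = c(0, 1, -0.01)),
               "increasing")
  expect_error(simulate_confocal_stack(shape = c(16, 16, 16),
                                       nucleus_radius = 10), "fit")
})

test_that("cohort generator controls censoring and hazard structure", {
  d0 <- simulate_cohort(50, 1, censor_rate = 0, seed = 2)
  expect_equal(sum(d0$event), 50)
  expect_true(all(d0$time > 0))
  d <- simulate_cohort(400, 3, 0.2, seed = 6)
  expect_equal(sum(d$arm == "low"), 100)
  # low expressors with triple hazard die faster
  expect_lt(median(d$time[d$arm == "low"]), median(d$time[d$arm == "high"]))
  expect_error(simulate_cohort(4), "n must be")
  expect_error(simulate_cohort(20, hazard_ratio_low_vs_high = 0), "hazard")
})

test_that("intensity table generator plants exactly the requested DEPs", {
  tab <- simulate_intensity_table(n_proteins = 100, n_enriched = 30,
                                  pseudo = 1, seed = 7)
  expect_equal(nrow(tab), 100)
  expect_equal(sum(tab$enriched), 30)
  fe <- fold_enrichment(tab, pseudo = 1)
  expect_equal(sort(fe$fold[match(tab$protein_id, fe$protein_id)]),
               sort(tab$true_fold), tolerance = 1e-12)
})
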