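test_that("gain curve fitting is exact on triplets and robust to noise", {
  fwd <- function(x) 10 + 0.5 * x + 0.001 * x^2
  cal <- data.frame(input = c(100, 500, 1000), output = fwd(c(100, 500, 1000)))
  fit <- fit_gain_curve(cal)
  expect_equal(fit$a0, 10, tolerance = 1e-9)
  expect_equal(fit$a1, 0.5, tolerance = 1e-9)
  expect_equal(fit$a2, 0.001, tolerance = 1e-9)
  ident <- fit_gain_curve(data.frame(input = c(1, 2, 3), output = c(1, 2, 3)))
  expect_equal(c(ident$a0, ident$a1, ident$a2), c(0, 1, 0), tolerance = 1e-12)
  # with 1%-of-y noise the estimator is unbiased: averaged over replicates
  # from one seeded stream the coefficients come back within 5%
  set.seed(8)
  x <- seq(50, 1500, length.out = 20)
  fits <- replicate(30, {
    noisy <- data.frame(input = x, output = fwd(x) * (1 + rnorm(20, 0, 0.01)))
    nf <- fit_gain_curve(noisy)
    c(nf$a0, nf$a1, nf$a2)
  })
  expect_equal(rowMeans(fits)[2], 0.5, tolerance = 0.05)
  expect_equal(rowMeans(fits)[3], 0.001, tolerance = 0.05)
  # every single replicate pins the quadratic coefficient to ~2% precision
  expect_lt(max(abs(fits[3, ] / 0.001 - 1)), 0.1)
  expect_error(fit_gain_curve(cal[1:2, ]), "3 calibration")
  expect_error(fit_gain_curve(data.frame(input = c(1, 1, 2),
                                         output = c(1, 2, 3))), "distinct")
  expect_warning(fit_gain_curve(data.frame(input = c(0, 1, 2),
                                           output = c(0, 5, 2))),
                 "increasing")
})

test_that("gain inversion picks the in-range root and round-trips", {
  cv <- gain_curve(10, 0.5, 0.001, c(0, 2000))
  # forward of 400 is 10 + 200 + 160 = 370; inversion recovers 400
  expect_equal(apply_gain(400, cv), 370)
  expect_equal(as.numeric(normalize_intensity(370, cv)), 400,
               tolerance = 1e-9)
  x <- seq(0, 2000, length.out = 101)
  back <- normalize_intensity(apply_gain(x, cv), cv)
  expect_equal(as.numeric(back), x, tolerance = 1e-6)
  ident <- gain_curve(0, 1, 0, c(-1e6, 1e6))
  arr <- array(rnorm(24), c(2, 3, 4))
  expect_equal(normalize_intensity(arr, ident), arr,
               ignore_attr = "n_flagged")
  # outputs below the curve's range are flagged, not silently kept
  expect_warning(bad <- normalize_intensity(-50, cv), "flagged")
  expect_true(is.na(bad[1]))
})

test_that("segmentation recovers nucleus, shell and their geometry", {
  sim <- simulate_confocal_stack(shape = c(64, 64, 64),
                                 voxel_size = c(0.4, 0.4, 0.4),
                                 nucleus_radius = 8, noise_sd = 0, seed = 1)
  m <- segment_masks(sim$raw)
  expect_equal(m$nuclear_radius_estimate, 8, tolerance = 0.03)
  shell_vol <- sum(m$perinuclear_shell) * 0.4^3
  expect_equal(shell_vol, 4 / 3 * pi * (10^3 - 8^3), tolerance = 0.05)
  expect_false(any(m$perinuclear_shell & m$nuclear))
  expect_false(any(m$cytoplasm & m$nuclear))
  expect_error(segment_masks(sim$raw, dapi_channel = "missing"), "channel")
})

test_that("shell and cytoplasm means match a brute-force voxel loop", {
  sim <- simulate_confocal_stack(shape = c(28, 36, 36), nucleus_radius = 3,
                                 perinuclear_enrichment = 2,
                                 gain_coeffs = c(5, 0.8, 2e-4),
                                 noise_sd = 0, seed = 3)
  res <- shell_and_cytoplasm_means(sim$raw, sim$masks, curve = sim$gain)
  expect_equal(res$shell_over_cytoplasm, 2, tolerance = 0.02)
  img <- normalize_intensity(sim$raw$channels$tubulin, sim$gain)
  acc <- 0; n <- 0
  idx <- which(sim$masks$perinuclear_shell)
  for (i in idx) { acc <- acc + img[i]; n <- n + 1 }
  expect_equal(res$shell_mean, acc / n, tolerance = 1e-12)
  expect_error(shell_and_cytoplasm_means(
    sim$raw, shell_masks(sim$masks$nuclear,
                         array(FALSE, dim(sim$masks$nuclear)),
                         sim$masks$perinuclear_shell, 3)), "empty")
})

test_that("shell voxelization error shrinks with voxel size", {
  ana <- 4 / 3 * pi * (5^3 - 4^3)
  coarse <- simulate_confocal_stack(shape = c(18, 26, 26),
                                    voxel_size = c(1, 0.9, 0.9),
                                    nucleus_radius = 4, seed = 2)
  fine <- simulate_confocal_stack(shape = c(36, 52, 52),
                                  voxel_size = c(0.5, 0.45, 0.45),
                                  nucleus_radius = 4, seed = 2)
  e1 <- abs(sum(segment_masks(coarse$raw)$perinuclear_shell) *
              prod(c(1, 0.9, 0.9)) / ana - 1)
  e2 <- abs(sum(segment_masks(fine$raw)$perinuclear_shell) *
              prod(c(0.5, 0.45, 0.45)) / ana - 1)
  expect_lt(e2, e1)
})

test_that("densitometric fold change and ratio normalization", {
  rec <- data.frame(condition = c("shRNA", "shRNA", "ctl", "ctl"),
                    ac_tubulin = c(200, 50, 120, 100),
                    beta_tubulin = c(100, 100, 100, 100),
                    treated = c(TRUE, FALSE, TRUE, FALSE))
  f <- msa_fold_change(rec)
  expect_equal(unname(f["shRNA"]), 4)
  expect_equal(unname(f["ctl"]), 1.2)
  # equal treated/untreated bands give fold 1
  same <- data.frame(condition = "c", ac_tubulin = c(80, 80),
                     beta_tubulin = c(90, 90), treated = c(TRUE, FALSE))
  expect_equal(unname(msa_fold_change(same)), 1)
  # doubling both beta bands leaves the fold unchanged
  rec2 <- rec; rec2$beta_tubulin <- rec2$beta_tubulin * 2
  expect_equal(msa_fold_change(rec2), f)
  expect_error(msa_fold_change(transform(rec, beta_tubulin = 0)), "> 0")
  expect_equal(ratio_normalize(1500, 3), 500)
  expect_equal(ratio_normalize(0.42, 0.42), 1)
  expect_equal(ratio_normalize(7 * 2, 3 * 2), ratio_normalize(7, 3))
  expect_error(ratio_normalize(1, 0), "> 0")
})
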