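#' Contractile traction dipole specification
#'
#' Ground-truth generator primitive for synthetic traction scenes: two
#' equal-and-opposite force patches ("poles") pulling toward their common
#' center, as a polarized contractile cell does.  Each pole's force is
#' spread over a Gaussian patch so the field stays band-limited on the
#' grid.
#'
#' @param center 2-vector, um.
#' @param axis_angle Dipole axis, radians.
#' @param force_magnitude Force per pole, pN, >= 0.
#' @param separation Pole separation, um, > 0.
#' @param patch_radius Gaussian patch sd, um, > 0.
#' @return Object of class `dipole_spec`.
#' @export
dipole_spec <- function(center, axis_angle = 0, force_magnitude = 100,
                        separation = 20, patch_radius = 2) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (separation <= 0) stop("separation must be > 0")
  if (force_magnitude < 0) stop("force_magnitude must be >= 0")
  if (patch_radius <= 0) stop("patch_radius must be > 0")
  structure(list(center = as.numeric(center), axis_angle = axis_angle,
                 force_magnitude = force_magnitude, separation = separation,
                 patch_radius = patch_radius),
            class = "dipole_spec")
}

dipole_poles <- function(dp) {
  dir <- c(cos(dp$axis_angle), sin(dp$axis_angle))
  list(pos = rbind(dp$center + dp$separation / 2 * dir,
                   dp$center - dp$separation / 2 * dir),
       # poles pull toward the center: contractile by construction
       force = rbind(-dp$force_magnitude * dir, dp$force_magnitude * dir))
}

#' Simulate a traction-force-microscopy scene
#'
#' Builds a ground-truth traction field from contractile dipoles, solves
#' the forward elastic problem for the bead displacements, adds i.i.d.
#' zero-mean Gaussian displacement noise, and returns a convex-hull cell
#' contour enclosing all poles with a stated margin.  Pole weights are
#' normalized by their discrete sum, so each generated field has net force
#' exactly zero by construction.
#'
#' @param dipoles List of [dipole_spec()] objects (possibly empty).
#' @param gel A [gel_substrate()].
#' @param grid A [grid_spec()].
#' @param noise_sd Displacement noise sd, um, >= 0.
#' @param seed Integer seed (identical seeds give identical scenes), or NULL to draw from the current RNG stream.
#' @param mask_margin Contour margin around the poles, um; default
#'   `3 * max(patch_radius) + 2 * spacing`.
#' @return List with `traction` (ground truth), `displacement`, `mask`.
#' @export
simulate_traction_scene <- function(dipoles, gel, grid, noise_sd = 0,
                                    seed = 1, mask_margin = NULL) {
  stopifnot(inherits(gel, "gel_substrate"), inherits(grid, "grid_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ax <- grid_axes(grid)
  xy <- grid_xy(grid)
  dA <- grid$spacing^2
  tx <- ty <- matrix(0, grid$shape[1], grid$shape[2])
  all_poles <- NULL
  for (dp in dipoles) {
    stopifnot(inherits(dp, "dipole_spec"))
    pp <- dipole_poles(dp)
    for (k in 1:2) {
      p <- pp$pos[k, ]
      if (p[1] < min(ax$x) || p[1] > max(ax$x) ||
          p[2] < min(ax$y) || p[2] > max(ax$y))
        stop(sprintf("dipole pole (%.1f, %.1f) um lies outside the grid",
                     p[1], p[2]))
      w <- exp(-((xy$x - p[1])^2 + (xy$y - p[2])^2) / (2 * dp$patch_radius^2))
      w <- w / (sum(w) * dA)           # discrete integral of w * dA == 1
      tx <- tx + pp$force[k, 1] * w
      ty <- ty + pp$force[k, 2] * w
    }
    all_poles <- rbind(all_poles, pp$pos)
  }
  traction <- traction_field(grid, tx, ty)
  u0 <- forward_solve(traction, gel)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- prod(grid$shape)
    u0$ux <- u0$ux + matrix(stats::rnorm(n, 0, noise_sd), grid$shape[1])
    u0$uy <- u0$uy + matrix(stats::rnorm(n, 0, noise_sd), grid$shape[1])
  }
  if (is.null(all_poles)) {
    mask <- cell_mask(raster = matrix(TRUE, grid$shape[1], grid$shape[2]),
                      grid = grid)
  } else {
    if (is.null(mask_margin))
      mask_margin <- 3 * max(vapply(dipoles, `[[`, numeric(1),
                                    "patch_radius")) + 2 * grid$spacing
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    ring <- cbind(cos(th), sin(th)) * mask_margin
    pts <- do.call(rbind, lapply(seq_len(nrow(all_poles)), function(i)
      sweep(ring, 2, all_poles[i, ], `+`)))
    hull <- pts[grDevices::chull(pts), ]
    mask <- cell_mask(polygon = hull, grid = grid)
  }
  list(traction = traction, displacement = u0, mask = mask)
}

#' Simulate microtubule length traces
#'
#' Multiplicative log-normal random walk:
#' `L[k+1] = L[k] * exp(dynamicity * Z)`, reflected at a small positive
#' floor, starting at `base_length`.  The generative model is a stand-in
#' with tunable dynamicity; only the measurement statistic is under test.
#' Traces are grouped 2-3 per cell, as in typical acquisitions.
#'
#' @param n_traces Number of microtubules.
#' @param n_frames Frames per trace, >= 2 (default 10).
#' @param frame_interval Seconds between frames (default 3; 10 frames span
#'   the canonical 30 s acquisition window).
#' @param base_length Starting length, um.
#' @param dynamicity Per-frame relative step scale, >= 0.
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @param floor_um Reflection floor, um.
#' @return List of [mt_trace()] objects.
#' @export
simulate_mt_traces <- function(n_traces, n_frames = 10, frame_interval = 3,
                               base_length = 10, dynamicity = 0.1, seed = 1,
                               floor_um = 0.2) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (dynamicity < 0) stop("dynamicity must be >= 0")
  if (base_length <= floor_um) stop("base_length must exceed the floor")
  if (!is.null(seed)) set.seed(as.integer(seed))
  per_cell <- sample(2:3, n_traces, replace = TRUE)
  cell_of <- rep(seq_len(n_traces), times = per_cell)[seq_len(n_traces)]
  lapply(seq_len(n_traces), function(i) {
    L <- numeric(n_frames)
    L[1] <- base_length
    if (n_frames > 1) {
      steps <- stats::rnorm(n_frames - 1, 0, dynamicity)
      for (k in 2:n_frames) {
        val <- L[k - 1] * exp(steps[k - 1])
        if (val < floor_um) val <- floor_um^2 / val   # multiplicative reflection
        L[k] <- val
      }
    }
    mt_trace(L, frame_interval = frame_interval,
             cell_id = sprintf("cell%03d", cell_of[i]),
             mt_id = sprintf("mt%03d", i))
  })
}

#' Simulate a two-channel confocal stack with perinuclear enrichment
#'
#' Ground truth: the DAPI channel is a solid ellipsoidal nucleus; the
#' tubulin channel is a cytoplasmic baseline inside a larger cell
#' ellipsoid, multiplied by `perinuclear_enrichment` inside the true
#' perinuclear shell (anisotropy-aware distance `0 < d <=
#' shell_fraction * equivalent radius` from the nuclear mask).  The raw
#' stack applies the quadratic detector-gain polynomial to the true
#' intensities and adds Gaussian noise.  Calibration `(input, output)`
#' pairs spanning the intensity range are emitted for gain-curve fitting.
#'
#' @param shape Stack shape `(nz, ny, nx)` voxels.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param nucleus_radius Nuclear semi-axes, um; scalar for a sphere or a
#'   3-vector `(z, y, x)`.
#' @param perinuclear_enrichment Shell over cytoplasm intensity factor,
#'   >= 1.
#' @param gain_coeffs `(a0, a1, a2)` of the detector polynomial; must be
#'   strictly increasing over the generated intensity range.
#' @param noise_sd Additive intensity noise sd on the raw stack.
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @param shell_fraction Shell thickness fraction of the nuclear radius.
#' @param cell_radius_factor Cell semi-axes as a multiple of the nuclear
#'   ones (default 1.35, capped to the stack).
#' @param intensities Named list of baseline levels: `background`,
#'   `cytoplasm`, `dapi`.
#' @return List with `raw` and `truth` ([voxel_stack()]s), `masks`
#'   (ground-truth [shell_masks()]), `calibration` (data frame), and
#'   `gain` (the [gain_curve()] used).
#' @export
simulate_confocal_stack <- function(shape = c(64, 64, 64),
                                    voxel_size = c(0.4, 0.4, 0.4),
                                    nucleus_radius = 8,
                                    perinuclear_enrichment = 2,
                                    gain_coeffs = c(0, 1, 0),
                                    noise_sd = 0,
                                    seed = 1,
                                    shell_fraction = 0.25,
                                    cell_radius_factor = 1.35,
                                    intensities = list(background = 5,
                                                       cytoplasm = 100,
                                                       dapi = 200)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8), length(voxel_size) == 3,
            all(voxel_size > 0))
  if (perinuclear_enrichment < 1) stop("perinuclear_enrichment must be >= 1")
  nr <- if (length(nucleus_radius) == 1) rep(nucleus_radius, 3) else
    as.numeric(nucleus_radius)
  if (length(nr) != 3 || any(nr <= 0)) stop("nucleus_radius must be scalar or 3-vector > 0")
  half_extent <- shape * voxel_size / 2
  if (any(nr >= half_extent))
    stop("nucleus does not fit inside the stack")
  r_eq <- prod(nr)^(1 / 3)
  thick <- shell_fraction * r_eq
  # physical coordinates of voxel centers, relative to the stack center
  ax <- lapply(1:3, function(i)
    (seq_len(shape[i]) - (shape[i] + 1) / 2) * voxel_size[i])
  Z <- array(ax[[1]], shape)
  Y <- aperm(array(ax[[2]], shape[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(ax[[3]], shape[c(3, 2, 1)]), c(3, 2, 1))
  rho <- sqrt((Z / nr[1])^2 + (Y / nr[2])^2 + (X / nr[3])^2)
  nuc <- rho <= 1
  cr <- pmin(nr * cell_radius_factor + thick + 1, half_extent * 0.98)
  cell <- (Z / cr[1])^2 + (Y / cr[2])^2 + (X / cr[3])^2 <= 1
  if (length(unique(nr)) == 1) {
    # spherical nucleus: continuous-geometry shell, R < r <= R + thickness
    shell <- rho > 1 & rho * nr[1] <= nr[1] + thick
  } else {
    # ellipsoid: voxel-space dilation of the nuclear mask (O(h) bias)
    shell <- dilate_ball3(nuc, thick, voxel_size) & !nuc
  }
  cyto <- cell & !nuc & !shell   # disjoint compartments by construction
  bg <- intensities$background
  tub_true <- array(bg, shape)
  tub_true[cyto] <- intensities$cytoplasm
  tub_true[shell & cell] <- intensities$cytoplasm * perinuclear_enrichment
  dapi_true <- array(bg, shape)
  dapi_true[nuc] <- intensities$dapi
  rng <- range(c(tub_true, dapi_true))
  rng <- rng + c(-0.05, 0.05) * diff(rng)
  a0 <- gain_coeffs[1]; a1 <- gain_coeffs[2]; a2 <- gain_coeffs[3]
  if (min(a1 + 2 * a2 * rng) <= 0)
    stop("gain curve is not strictly increasing on the generated intensity range")
  curve <- gain_curve(a0, a1, a2, rng)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mk_raw <- function(tr) {
    r <- apply_gain(tr, curve)
    if (noise_sd > 0) r <- r + array(stats::rnorm(length(r), 0, noise_sd), dim(r))
    r
  }
  raw <- voxel_stack(list(dapi = mk_raw(dapi_true), tubulin = mk_raw(tub_true)),
                     voxel_size)
  truth <- voxel_stack(list(dapi = dapi_true, tubulin = tub_true), voxel_size)
  masks <- shell_masks(nuc, cyto, shell & cell, r_eq)
  cal_in <- seq(rng[1], rng[2], length.out = 9)
  calibration <- data.frame(input = cal_in, output = apply_gain(cal_in, curve))
  list(raw = raw, truth = truth, masks = masks, calibration = calibration,
       gain = curve)
}

#' Simulate a two-arm survival cohort
#'
#' Exponential event times whose hazard depends on whether the subject's
#' expression falls below its 25th percentile (the "low" arm); a
#' `hazard_ratio_low_vs_high > 1` makes low expressors die faster.
#' Censoring marks a random fraction of subjects as censored uniformly
#' before their event time.
#'
#' @param n Subjects, >= 8.
#' @param hazard_ratio_low_vs_high Hazard ratio of low vs high expressors,
#'   > 0 (1 = null).
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @param median_survival_high Median survival of the high arm, months
#'   (sets the baseline hazard; default 60).
#' @return Data frame: `subject_id`, `expression`, `time` (months),
#'   `event` (logical), `arm` ("low"/"high" ground truth).
#' @export
simulate_cohort <- function(n, hazard_ratio_low_vs_high = 1,
                            censor_rate = 0.2, seed = 1,
                            median_survival_high = 60) {
  if (n < 8) stop("n must be >= 8")
  if (hazard_ratio_low_vs_high <= 0) stop("hazard ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr <- stats::rnorm(n)
  low <- expr < stats::quantile(expr, 0.25, type = 7)
  h0 <- log(2) / median_survival_high
  rate <- h0 * ifelse(low, hazard_ratio_low_vs_high, 1)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  time <- pmax(time, 1e-6)
  data.frame(subject_id = sprintf("s%04d", seq_len(n)),
             expression = expr,
             time = time,
             event = !censored,
             arm = ifelse(low, "low", "high"))
}

#' Simulate a bait/control protein intensity table
#'
#' Builds an interactome-style label-free intensity table with a known
#' number of truly enriched proteins: target fold enrichments are drawn
#' above and below the threshold and bait intensities constructed so the
#' pseudo-counted fold `(bait + pseudo) / (control + pseudo)` equals the
#' target exactly in the noiseless case.
#'
#' @param n_proteins Total proteins (default 417).
#' @param n_enriched Proteins with true fold >= `threshold` (default 130).
#' @param threshold Enrichment cut (default 2).
#' @param pseudo Pseudo-count the folds are constructed around (default 1).
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Data frame: `protein_id`, `bait_intensity`, `control_intensity`,
#'   `category`, `true_fold`, `enriched`.
#' @export
simulate_intensity_table <- function(n_proteins = 417, n_enriched = 130,
                                     threshold = 2, pseudo = 1, seed = 1) {
  stopifnot(n_enriched <= n_proteins, n_proteins >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  control <- stats::rlnorm(n_proteins, meanlog = log(5e3), sdlog = 1) + 10
  fold <- numeric(n_proteins)
  enriched <- seq_len(n_proteins) <= n_enriched
  fold[enriched] <- stats::runif(n_enriched, threshold, 8 * threshold)
  fold[!enriched] <- stats::runif(n_proteins - n_enriched,
                                  0.1, 0.95 * threshold)
  bait <- fold * (control + pseudo) - pseudo
  cats <- c("tubulin", "MT-associated", "motor", "other")
  category <- sample(cats, n_proteins, replace = TRUE,
                     prob = c(0.15, 0.2, 0.1, 0.55))
  ord <- sample(n_proteins)   # shuffle so enriched rows are not contiguous
  data.frame(protein_id = sprintf("P%05d", seq_len(n_proteins)),
             bait_intensity = bait,
             control_intensity = control,
             category = category,
             true_fold = fold,
             enriched = enriched)[ord, ]
}

#' Simulate a two-arm traction-force-microscopy study
#'
#' Builds and analyzes a synthetic control-vs-silenced cohort across gel
#' stiffnesses: control cells are polarized dipole pairs whose anisotropy
#' grows with substrate stiffness; "silenced" cells are near-isotropic
#' orthogonal dipole pairs whose pole forces are derived so their traction
#' magnitude is `magnitude_factor` (default 40% lower) times the control
#' arm's.  Each scene is inverted with the cell-contour constraint at an
#' L-curve-selected regularization weight and summarized per cell.
#'
#' @param n_per_arm Cells per arm and stiffness (default 20).
#' @param stiffness_kpa Gel stiffnesses in kPa (defaults 1, 11, 26).
#' @param magnitude_factor Silenced-to-control traction magnitude ratio
#'   (default 0.6).
#' @param noise_sd Bead displacement noise sd, um (default 0.005, typical
#'   sub-pixel tracking precision).
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Data frame, one row per cell: `stiffness_kpa`, `arm`, `rms_Pa`,
#'   `polarity`, `orientation_rad`, `ncm_pNum`, `area_um2`.
#' @export
simulate_tfm_study <- function(n_per_arm = 20, stiffness_kpa = c(1, 11, 26),
                               magnitude_factor = 0.6, noise_sd = 0.005,
                               seed = 1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- grid_spec(2, c(48, 48))
  ext <- 48 * 2
  # control traction anisotropy (secondary/primary dipole force) falls, and
  # pole force rises, with substrate stiffness, as polarized cells do
  anis_tab <- stats::approxfun(c(1, 11, 26), c(0.6, 0.35, 0.2), rule = 2)
  force_tab <- stats::approxfun(c(1, 11, 26), c(2000, 15000, 30000), rule = 2)
  rows <- vector("list", 0)
  for (E in stiffness_kpa) for (arm in c("control", "silenced")) {
    gel <- gel_substrate(E * 1e3)
    a <- anis_tab(E)
    for (i in seq_len(n_per_arm)) {
      f0 <- force_tab(E) * exp(stats::rnorm(1, 0, 0.15))
      th <- stats::runif(1, 0, pi)
      ctr <- c(ext / 2, ext / 2) + stats::runif(2, -6, 6)
      if (arm == "control") {
        dips <- list(dipole_spec(ctr, th, f0, 20, 4),
                     dipole_spec(ctr, th + pi / 2, f0 * a, 20, 4))
      } else {
        # orthogonal near-equal pair with RMS = magnitude_factor x control
        fs <- magnitude_factor * f0 * sqrt((1 + a^2) / 2)
        dips <- list(dipole_spec(ctr, th, fs, 20, 4),
                     dipole_spec(ctr, th + pi / 2,
                                 fs * exp(stats::rnorm(1, 0, 0.08)), 20, 4))
      }
      sc <- simulate_traction_scene(dips, gel, grid, noise_sd = noise_sd,
                                    seed = NULL)
      lam <- select_lambda_lcurve(sc$displacement, gel)$lambda
      trac <- constrained_inverse(sc$displacement, sc$mask, gel,
                                  reg_lambda = lam)
      s <- summarize_cell(trac, sc$mask)
      rows[[length(rows) + 1]] <-
        data.frame(stiffness_kpa = E, arm = arm, rms_Pa = s$rms_traction,
                   polarity = s$polarity, orientation_rad = s$orientation,
                   ncm_pNum = s$net_contractile_moment,
                   area_um2 = s$spread_area)
    }
  }
  do.call(rbind, rows)
}
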