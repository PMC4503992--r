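#' Multi-channel confocal voxel stack
#'
#' Named 3-D intensity arrays sharing one shape, with physical voxel sizes.
#' Array dimensions are ordered `(z, y, x)` to match serial optical
#' sectioning.
#'
#' @param channels Named list of 3-D numeric arrays of identical shape.
#' @param voxel_size Length-3 numeric, um per voxel along `(z, y, x)`.
#' @return Object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, voxel_size) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3))
    stop("each channel must be a 3-D array (z, y, x)")
  if (length(unique(lapply(dims, as.integer))) != 1)
    stop("all channels must share one shape")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (z, y, x), um")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "voxel_stack")
}

#' Detector gain calibration curve
#'
#' Second-order polynomial detector response
#' `y = a2 x^2 + a1 x + a0`, where y is the recorded (output) intensity
#' and x the underlying (input) intensity.  Must be strictly increasing on
#' its valid range so it can be inverted voxel-wise.
#'
#' @param a0,a1,a2 Polynomial coefficients.
#' @param valid_range Length-2 input-intensity interval the curve is
#'   trusted (and invertible) on.
#' @return Object of class `gain_curve`.
#' @export
gain_curve <- function(a0, a1, a2, valid_range) {
  stopifnot(is.numeric(valid_range), length(valid_range) == 2,
            valid_range[1] < valid_range[2])
  dmin <- min(a1 + 2 * a2 * valid_range)
  if (dmin <= 0)
    stop("gain curve must be strictly increasing on valid_range")
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 valid_range = as.numeric(valid_range)),
            class = "gain_curve")
}

#' Apply a gain curve (forward detector model)
#'
#' @param x Input intensities.
#' @param curve A [gain_curve()].
#' @return Output intensities `a2 x^2 + a1 x + a0`.
#' @export
apply_gain <- function(x, curve) {
  stopifnot(inherits(curve, "gain_curve"))
  curve$a2 * x^2 + curve$a1 * x + curve$a0
}

#' Fit a quadratic gain curve to calibration pairs
#'
#' Least-squares quadratic through `(input, output)` intensity pairs, e.g.
#' matched acquisitions at detector gains of 600/700/800 V.  With exactly
#' three distinct pairs the fit interpolates them exactly.  Monotonicity is
#' checked on the calibration input range and violations warn.
#'
#' @param calibration Data frame or matrix with columns `input`, `output`
#'   (first two columns used if unnamed); >= 3 pairs, distinct inputs.
#' @return A [gain_curve()] whose `valid_range` is the input range.
#' @export
fit_gain_curve <- function(calibration) {
  m <- as.data.frame(calibration)
  if (all(c("input", "output") %in% names(m))) {
    x <- m$input; y <- m$output
  } else {
    x <- m[[1]]; y <- m[[2]]
  }
  if (length(x) < 3) stop("need at least 3 calibration pairs")
  if (anyDuplicated(x)) stop("calibration inputs must be distinct")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  a0 <- cf[1]; a1 <- cf[2]; a2 <- cf[3]
  rng <- range(x)
  if (min(a1 + 2 * a2 * rng) <= 0) {
    warning("fitted gain curve is not strictly increasing on the calibration range")
    return(structure(list(a0 = a0, a1 = a1, a2 = a2,
                          valid_range = rng),
                     class = "gain_curve"))
  }
  gain_curve(a0, a1, a2, rng)
}

#' Invert the gain curve on a channel (gain normalization)
#'
#' Maps recorded intensities back to input intensities by solving the
#' quadratic per voxel, keeping the root inside the curve's valid range
#' (the increasing branch).  Voxels with no real root in range become NA
#' and are excluded from downstream means.
#'
#' @param channel Numeric array of recorded intensities.
#' @param curve A [gain_curve()].
#' @return Array of normalized intensities (NA where non-invertible), with
#'   attribute `n_flagged` counting excluded voxels.
#' @export
normalize_intensity <- function(channel, curve) {
  stopifnot(inherits(curve, "gain_curve"))
  a0 <- curve$a0; a1 <- curve$a1; a2 <- curve$a2
  y <- channel
  if (abs(a2) < .Machine$double.eps) {
    x <- (y - a0) / a1
  } else {
    disc <- a1^2 - 4 * a2 * (a0 - y)
    x <- array(NA_real_, dim = dim(y) %||% length(y))
    ok <- disc >= 0
    # increasing branch: derivative a1 + 2 a2 x > 0 <=> x > -a1/(2 a2) for
    # a2 > 0 (plus root), x < -a1/(2 a2) for a2 < 0 (also the plus root
    # after sign flip in the denominator); the "+sqrt" root is it either way
    x[ok] <- (-a1 + sqrt(disc[ok])) / (2 * a2)
  }
  lo <- curve$valid_range[1]; hi <- curve$valid_range[2]
  tol <- 1e-9 * max(1, abs(hi))
  out_of_range <- !is.na(x) & (x < lo - tol | x > hi + tol)
  x[out_of_range] <- NA_real_
  if (!is.null(dim(y))) dim(x) <- dim(y)
  n_flagged <- sum(is.na(x))
  if (n_flagged > 0)
    warning(n_flagged, " voxel(s) not invertible on the valid range; flagged NA")
  attr(x, "n_flagged") <- n_flagged
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# zero-filled shift of a 3-D logical/numeric array
shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  src_z <- seq_len(d[1]) - dz; src_y <- seq_len(d[2]) - dy
  src_x <- seq_len(d[3]) - dx
  okz <- src_z >= 1 & src_z <= d[1]
  oky <- src_y >= 1 & src_y <= d[2]
  okx <- src_x >= 1 & src_x <= d[3]
  out[okz, oky, okx] <- a[src_z[okz], src_y[oky], src_x[okx]]
  out
}

# 6-connected flood fill of `domain` starting from `seed`, vectorized
flood6 <- function(seed, domain) {
  cur <- seed & domain
  repeat {
    grown <- cur |
      shift3(cur, 1, 0, 0) | shift3(cur, -1, 0, 0) |
      shift3(cur, 0, 1, 0) | shift3(cur, 0, -1, 0) |
      shift3(cur, 0, 0, 1) | shift3(cur, 0, 0, -1)
    grown <- grown & domain
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# largest 6-connected component of a logical 3-D array
largest_component3 <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood6(seed, remaining)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) mask else best
}

# fill interior cavities: background is what border-connected flood reaches
fill_holes3 <- function(mask) {
  d <- dim(mask)
  seed <- array(FALSE, d)
  seed[1, , ] <- TRUE; seed[d[1], , ] <- TRUE
  seed[, 1, ] <- TRUE; seed[, d[2], ] <- TRUE
  seed[, , 1] <- TRUE; seed[, , d[3]] <- TRUE
  bg <- flood6(seed & !mask, !mask)
  mask | (!mask & !bg)
}

# voxels whose center lies within Euclidean distance <= dist of a mask
# voxel center (anisotropy-aware), via FFT convolution with a ball
# kernel; the center-to-center convention matches the standard binary
# dilation of image-analysis toolkits.
dilate_ball3 <- function(mask, dist, voxel_size) {
  d <- dim(mask)
  rz <- floor(dist / voxel_size[1]); ry <- floor(dist / voxel_size[2])
  rx <- floor(dist / voxel_size[3])
  kz <- (-rz):rz; ky <- (-ry):ry; kx <- (-rx):rx
  KZ <- array(kz * voxel_size[1], c(length(kz), length(ky), length(kx)))
  KY <- aperm(array(ky * voxel_size[2], c(length(ky), length(kz), length(kx))),
              c(2, 1, 3))
  KX <- aperm(array(kx * voxel_size[3], c(length(kx), length(ky), length(kz))),
              c(3, 2, 1))
  ball <- (KZ^2 + KY^2 + KX^2) <= dist^2 + 1e-9
  pd <- d + dim(ball) - 1L
  A <- array(0, pd); B <- array(0, pd)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  B[seq_len(dim(ball)[1]), seq_len(dim(ball)[2]), seq_len(dim(ball)[3])] <- ball
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    prod(pd)
  off <- c(rz, ry, rx)
  out <- conv[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
              off[3] + seq_len(d[3])] > 0.5
  out
}

#' Shell mask container
#'
#' @param nuclear,cytoplasm,perinuclear_shell Logical 3-D arrays of one
#'   shape; shell and nuclear masks must be disjoint.
#' @param nuclear_radius_estimate Equivalent-sphere nuclear radius, um.
#' @return Object of class `shell_masks`.
#' @export
shell_masks <- function(nuclear, cytoplasm, perinuclear_shell,
                        nuclear_radius_estimate) {
  stopifnot(identical(dim(nuclear), dim(cytoplasm)),
            identical(dim(nuclear), dim(perinuclear_shell)))
  if (any(perinuclear_shell & nuclear))
    stop("perinuclear shell must not intersect the nuclear mask")
  structure(list(nuclear = nuclear, cytoplasm = cytoplasm,
                 perinuclear_shell = perinuclear_shell,
                 nuclear_radius_estimate = nuclear_radius_estimate),
            class = "shell_masks")
}

#' Segment nuclear, cytoplasmic and perinuclear-shell masks
#'
#' Nuclear mask: Otsu global threshold on the DAPI channel, largest
#' 6-connected component, interior holes filled.  Cytoplasm: Otsu threshold
#' on the tubulin channel minus the nuclear mask.  The equivalent-sphere
#' nuclear radius is `(3V / 4 pi)^(1/3)` from the nuclear voxel volume.
#' The perinuclear shell is the hollow volume adjacent to the nucleus:
#' voxels at anisotropy-aware Euclidean distance `0 < d <= shell_fraction *
#' radius` from the nuclear surface.  One cell per field is assumed.
#'
#' @param stack A [voxel_stack()].
#' @param dapi_channel,tubulin_channel Channel names (defaults "dapi",
#'   "tubulin").
#' @param shell_fraction Shell thickness as a fraction of the nuclear
#'   radius; default 0.25 (~1/4 of the average nuclear radius).
#' @param reference_radius Optional cohort-average nuclear radius (um) to
#'   use for the shell thickness instead of this cell's estimate.
#' @return A [shell_masks()] object.
#' @export
segment_masks <- function(stack, dapi_channel = "dapi",
                          tubulin_channel = "tubulin",
                          shell_fraction = 0.25,
                          reference_radius = NULL) {
  stopifnot(inherits(stack, "voxel_stack"))
  for (ch in c(dapi_channel, tubulin_channel))
    if (!ch %in% names(stack$channels)) stop("missing channel: ", ch)
  dapi <- stack$channels[[dapi_channel]]
  tub <- stack$channels[[tubulin_channel]]
  nuc <- dapi > otsu_threshold(dapi)
  if (!any(nuc)) stop("empty nuclear mask after thresholding")
  nuc <- fill_holes3(largest_component3(nuc))
  vox_vol <- prod(stack$voxel_size)
  radius <- (3 * sum(nuc) * vox_vol / (4 * pi))^(1 / 3)
  thick <- shell_fraction * (reference_radius %||% radius)
  shell <- dilate_ball3(nuc, thick, stack$voxel_size) & !nuc
  # cytoplasm and shell are reported as disjoint compartments
  cyto <- (tub > otsu_threshold(tub)) & !nuc & !shell
  shell_masks(nuc, cyto, shell, radius)
}

#' Mean gain-normalized intensity in cytoplasm and perinuclear shell
#'
#' Averages the (optionally gain-normalized) tubulin intensity over the
#' cytoplasmic mask and over the perinuclear shell; NA-flagged voxels are
#' excluded.
#'
#' @param stack A [voxel_stack()].
#' @param masks A [shell_masks()].
#' @param curve Optional [gain_curve()]; when given, intensities are
#'   inverted through it first.
#' @param channel Channel name, default "tubulin".
#' @return List with `cytoplasm_mean`, `shell_mean`, and their ratio
#'   `shell_over_cytoplasm`.
#' @export
shell_and_cytoplasm_means <- function(stack, masks, curve = NULL,
                                      channel = "tubulin") {
  stopifnot(inherits(stack, "voxel_stack"), inherits(masks, "shell_masks"))
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("missing channel: ", channel)
  if (!is.null(curve)) img <- suppressWarnings(normalize_intensity(img, curve))
  if (!any(masks$cytoplasm) || !any(masks$perinuclear_shell))
    stop("empty cytoplasm or shell mask")
  cm <- mean(img[masks$cytoplasm], na.rm = TRUE)
  sm <- mean(img[masks$perinuclear_shell], na.rm = TRUE)
  list(cytoplasm_mean = cm, shell_mean = sm,
       shell_over_cytoplasm = sm / cm)
}

#' Densitometric fold-change in tubulin acetylation
#'
#' Ac-tubulin band intensity is normalized to the matched beta-tubulin
#' band, and the treatment-induced fold increase is the treated over
#' untreated ratio of those normalized intensities.
#'
#' @param records Data frame with columns `condition`, `ac_tubulin`,
#'   `beta_tubulin`, `treated` (logical), one treated and one untreated
#'   row per condition.
#' @return Named numeric vector of folds, one per condition.
#' @export
msa_fold_change <- function(records) {
  d <- as.data.frame(records)
  req <- c("condition", "ac_tubulin", "beta_tubulin", "treated")
  if (!all(req %in% names(d))) stop("records need columns ", paste(req, collapse = ", "))
  if (any(d$beta_tubulin <= 0)) stop("beta-tubulin band intensity must be > 0")
  if (any(d$ac_tubulin <= 0)) stop("Ac-tubulin band intensity must be > 0")
  conds <- unique(d$condition)
  out <- vapply(conds, function(cc) {
    sub <- d[d$condition == cc, ]
    tr <- sub[sub$treated, ]; un <- sub[!sub$treated, ]
    if (nrow(tr) != 1 || nrow(un) != 1)
      stop("condition ", cc, " needs exactly one treated and one untreated record")
    (tr$ac_tubulin / tr$beta_tubulin) / (un$ac_tubulin / un$beta_tubulin)
  }, numeric(1))
  names(out) <- conds
  out
}

#' Ratio normalization
#'
#' Plain signal-over-reference ratio, used for fluorescence per protein
#' (AU/ug) and for viability relative to vehicle treatment.
#'
#' @param signal Numeric.
#' @param reference Positive numeric (recycled).
#' @return `signal / reference`.
#' @export
ratio_normalize <- function(signal, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be > 0")
  signal / reference
}
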