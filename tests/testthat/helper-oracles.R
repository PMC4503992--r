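# Independent brute-force oracles used across test files.  These stay
# deliberately naive (explicit loops, enumeration) so they cannot share a
# defect with the vectorized implementation paths they check.

# direct node-loop RMS over a raster mask
oracle_rms <- function(tf, inm) {
  acc <- 0; n <- 0
  for (i in seq_len(nrow(tf$tx))) for (j in seq_len(ncol(tf$tx))) {
    if (inm[i, j]) { acc <- acc + tf$tx[i, j]^2 + tf$ty[i, j]^2; n <- n + 1 }
  }
  sqrt(acc / n)
}

# direct node-loop symmetrized first moment about the traction-weighted
# centroid
oracle_moment <- function(tf, inm) {
  g <- tf$grid; h <- g$spacing
  xs <- g$origin[1] + (seq_len(g$shape[2]) - 1) * h
  ys <- g$origin[2] + (seq_len(g$shape[1]) - 1) * h
  sw <- swx <- swy <- 0
  for (i in seq_len(g$shape[1])) for (j in seq_len(g$shape[2])) if (inm[i, j]) {
    w <- sqrt(tf$tx[i, j]^2 + tf$ty[i, j]^2)
    sw <- sw + w; swx <- swx + w * xs[j]; swy <- swy + w * ys[i]
  }
  cx <- if (sw > 0) swx / sw else mean(xs)
  cy <- if (sw > 0) swy / sw else mean(ys)
  M <- matrix(0, 2, 2)
  for (i in seq_len(g$shape[1])) for (j in seq_len(g$shape[2])) if (inm[i, j]) {
    x <- c(xs[j] - cx, ys[i] - cy); t_ <- c(tf$tx[i, j], tf$ty[i, j])
    M <- M + (outer(x, t_) + outer(t_, x)) / 2 * h^2
  }
  M
}

# Kaplan-Meier by explicit at-risk/deaths tabulation
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1; out <- NULL
  for (t0 in ut) {
    d <- sum(times == t0 & events)
    n <- sum(times >= t0)
    s <- s * (1 - d / n)
    out <- rbind(out, c(time = t0, survival = s))
  }
  as.data.frame(out)
}

# two-sided Fisher p by direct enumeration over all tables with the
# observed margins, using factorial probabilities
oracle_fisher_p <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  prob <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(cc) - lfactorial(d))
  }
  p_obs <- prob(tb[1, 1])
  sum(vapply(0:min(r1, c1), function(a) {
    p <- prob(a); if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# rotate a square-grid vector field by 90 degrees counterclockwise about
# the grid center (explicit index loop)
rot90_field <- function(fx, fy) {
  n <- nrow(fx)
  gx <- gy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gx[i, j] <- -fy[n + 1 - j, i]
    gy[i, j] <- fx[n + 1 - j, i]
  }
  list(x = gx, y = gy)
}

# standard small TFM fixture: centered x-axis dipole on an 11 kPa gel
make_dipole_scene <- function(n = 64, spacing = 2, force = 100,
                              separation = 20, patch = 4, E = 1000,
                              noise_sd = 0, seed = 1) {
  gel <- gel_substrate(E, 0.5)
  grid <- grid_spec(spacing, c(n, n))
  ctr <- rep((n - 1) * spacing / 2, 2)
  dip <- dipole_spec(ctr, 0, force, separation, patch)
  c(simulate_traction_scene(list(dip), gel, grid, noise_sd = noise_sd,
                            seed = seed),
    list(gel = gel, grid = grid))
}
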